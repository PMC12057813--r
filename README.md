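# seedclust

De novo clustering of long-read transcriptome datasets (PacBio, Oxford
Nanopore) into gene families, for reference-free transcriptomics: split a
FASTQ of long reads into clusters that each collect the reads of one locus —
across isoforms, allele variants and both transcription directions — so that
error correction and isoform reconstruction can run per cluster. No
reference genome is used.

## Method

Reads are sketched with **canonical minimizers**: per window of `w`
consecutive k-mer start positions, the k-mer minimizing a hash-induced total
ordering is kept, with each position contributing the smaller hash of the
forward k-mer and its reverse complement (strand-independent seeds). Phred
qualities gate the seeds: with per-base correctness probability
`p_i = 1 − 10^(−q_i/10)`, a seed spanning `k` bases has confidence
`P = ∏ p_j`, and seeds with `P > T1` are **high-confidence seeds** (HCS).

Reads are sorted by decreasing HCS count and clustered greedily in one
pass. A read joins the cluster with which it shares the most seed values,
provided the shared fraction of its distinct seeds is at least `T2`;
otherwise it founds a new cluster. A cluster is represented by the **union
of its members' HCS**, updated dynamically as reads join — this lets
isoforms with different exon structures chain into a single gene-family
cluster, where a fixed founder-read representation would split them. An
optional **iterative merging** pass (`postCluster = TRUE`) joins clusters
whose HCS overlap exceeds `T3`, iterating to a fixpoint.

Technology presets: ONT `k=13, w=21, T1=0.95, T2=0.5, T3=0.5`; PacBio
`k=15, w=51, T1=0.98, T2=0.5, T3=0.8`.

The package also provides the standard external clustering metrics
(homogeneity, completeness, V-measure, Rand and adjusted Rand index,
computed from the contingency table with natural-log entropies) and a
synthetic long-read generator with ground-truth labels for end-to-end
validation.

## Worked example

```r
library(seedclust)

sim <- simulateReads(simConfig(nFamilies = 10, readsPerFamily = 50,
                               errorRate = 0.05, seed = 1))
cl <- runPipeline(sim$reads, outfolder = "out",
                  config = clusterConfig("ont", postCluster = TRUE))
#> sorted 500 reads [0.18s]
#> greedy clustering: 21 clusters from 500 reads [0.12s]
#> cluster merging: 21 -> 11 clusters in 2 sweep(s) [0.02s]
#> wrote out/final_clusters.tsv [0.01s]

truth <- sim$truth$family[match(names(readAssignments(cl)),
                                sim$truth$read_id)]
adjustedRandIndex(readAssignments(cl), truth)
#> [1] 0.9977783
```

500 simulated reads from 10 gene families at 5% error are sorted, clustered
and merged in under a second; the greedy pass leaves a few families split
(21 clusters), the merging pass collapses them to 11 (10 families plus one
singleton), and the clustering agrees with the ground truth at ARI 0.998.
`out/final_clusters.tsv` maps each read to a cluster (`cluster_id<TAB>read_id`,
ids renumbered by decreasing size) next to one FASTQ per cluster.

A thin command-line front end wraps the same functions:

```sh
inst/scripts/seedclust simulate --out sim --error-rate 0.05 --seed 4
inst/scripts/seedclust cluster  --fastq sim/reads.fastq --outfolder out \
                                --mode ont --post-cluster
inst/scripts/seedclust evaluate --clusters out/final_clusters.tsv \
                                --classes sim/truth.tsv
```

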