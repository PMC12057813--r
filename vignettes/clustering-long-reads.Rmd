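---
title: "Clustering long transcriptomic reads with quality-aware minimizers"
author: "seedclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering long transcriptomic reads with quality-aware minimizers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedclust)
```

## The problem

Long-read transcriptome sequencing (PacBio, Oxford Nanopore) can cover
transcripts end to end, but reference-free analysis of such data needs the
reads split into manageable, biologically coherent groups first. The task
this package addresses is de novo clustering of a long-read transcriptome
dataset by *gene family*: reads from the same locus — across isoforms, allele
variants and both transcription directions — should land in one cluster,
without any reference genome. Downstream steps (error correction, isoform
reconstruction) then operate per cluster.

Two properties of the data drive the design. First, transcripts from one
gene differ systematically (exon skipping, alternative starts and ends, 3'/5'
truncation from RNA degradation), so any fixed per-cluster "reference read"
under-represents the family. Second, per-base error rates vary widely within
and between reads, and the base caller tells us where: the Phred quality
string is an explicit per-base error model that can gate which sequence
features are trustworthy.

## The method

**Seeds.** Each read is sketched with minimizers: for every window of `w`
consecutive k-mer start positions, the k-mer with the smallest value under a
hash-induced total ordering is kept (leftmost on ties; a minimizer shared by
overlapping windows is emitted once). With canonical minimizers (the
default) each position contributes the smaller of the hash of the forward
k-mer and of its reverse complement, which makes seed values
strand-independent — reads transcribed in opposite directions still share
seeds.

**High-confidence seeds.** A Phred score $q_i$ gives the probability that
base $i$ was called correctly, $p_i = 1 - 10^{-q_i/10}$. The confidence of a
seed spanning positions $i..i+k-1$ is $P_i = \prod_{j=i}^{i+k-1} p_j$, the
probability that the whole k-mer is error-free. Seeds with $P_i > T_1$ are
*high-confidence seeds* (HCS). Everything downstream that represents a read
or a cluster uses only HCS; all seeds of a read are still used when deciding
how similar the read is to a cluster.

**Sorting.** Reads are ordered by decreasing HCS count (stable on ties), so
the reads carrying the most trustworthy information found the clusters.

**Greedy clustering with dynamic representations.** The sorted reads are
streamed once. The first read founds a cluster whose representation is its
HCS set. For each following read, an inverted index (seed value → cluster
ids) retrieves every cluster sharing at least one seed value; with $D$ the
number of distinct seed values of the read and $S$ the best shared count,
the read joins the best-sharing cluster if $S/D \ge T_2$ (ties: oldest
cluster), otherwise it founds a new cluster. On joining, the read's HCS that
are new to the cluster are added to the representation and the index. This
dynamic update is the method's central idea: an isoform that overlaps the
founder only partially still contributes its own exons' seeds, so a later
isoform overlapping *those* exons can join even if it shares little with the
founder.

**Iterative cluster merging (optional).** After the greedy pass, clusters
are visited in ascending order of representation size ($|hcs|$, not member
count); a visited cluster merges into the cluster sharing the most of its
HCS values — provided the target's representation is strictly larger (or
equal-sized with a smaller id) and the shared fraction relative to the
visited cluster exceeds $T_3$. Sweeps repeat until none merges. Within a
sweep, targets are evaluated against sweep-start snapshots; if a chosen
target was itself absorbed earlier in the same sweep, the merge is postponed
to the next sweep rather than redirected. Merging operates purely on
representations and member-id lists; read sequences are never reloaded.

## Parameters

| parameter | meaning | ONT preset | PacBio preset |
|-----------|---------|-----------:|--------------:|
| `k` | seed length (bases) | 13 | 15 |
| `w` | window size (k-mer start positions) | 21 | 51 |
| `t1` | HCS confidence threshold (strict) | 0.95 | 0.98 |
| `t2` | join threshold, shared/distinct-seeds fraction (inclusive) | 0.5 | 0.5 |
| `t3` | merge threshold, shared-HCS fraction (strict) | 0.5 | 0.8 |

The noisier the technology, the lower `t1` must sit for any seeds to qualify
at all; PacBio HiFi reads afford a stricter gate. The higher PacBio `t3`
guards against over-merging driven by artificial concatamers (multiple
transcripts fused into one read), a known artifact in some PacBio library
preparations. Merging is recommended for ONT data, where sparse HCS early in
the run fragment families that only later accumulate complete
representations; on HiFi data it rarely changes the result. Both even and
odd `w` are supported.

## Numerical and tie-breaking choices

* Seed values are produced by a splitmix64-style 64-bit avalanche hash of
  the 2-bit-encoded k-mer, masked to 53 bits so every value is exactly
  representable as an R double. The mask can introduce rare value ties
  between distinct k-mers; all orderings stay total because ties break
  leftmost. A lexicographic ("identity") ordering over the 2-bit encoding is
  available to make minimizer choices predictable in examples and tests.
  `k` is capped at 26 by the 2-bit packing.
* k-mers containing non-ACGT characters are excluded from candidacy; a
  window with no valid k-mer emits no seed. Reads shorter than `k` produce
  no seeds and found their own single-member clusters, as do reads whose
  seeds all fail `t1` gating when they also share nothing; such
  empty-representation clusters can never attract members or merge.
* Reads with fewer than `w` k-mer start positions are scanned as a single
  window.
* The join comparison is inclusive (`>= t2`) so that `t2 = 1` still lets
  exact duplicates join; the HCS and merge comparisons are strict (`> t1`,
  `> t3`), so `t1 = 1` selects nothing and `t3 = 1` disables merging.
* Canonical seed confidences always use the forward-read quality substring:
  qualities describe the sequenced bases regardless of which strand's k-mer
  won the canonical comparison.
* Strand symmetry holds for the *set* of canonical seed values of a read.
  The positional multiset can differ between a read and its reverse
  complement in one edge case — adjacent k-mers that are mutual reverse
  complements produce tied canonical values whose per-window collapse
  depends on orientation near read ends. Cluster representations are sets,
  so this has no downstream effect.
* Output cluster ids in `final_clusters.tsv` are renumbered by decreasing
  member count (ties: creation order); the id convention of the internal
  objects is creation order.

## The synthetic benchmark generator

`simulateReads()` produces the data the algorithm is designed for, at desk
scale, with ground truth:

* **Families** are independent random exon chains (default 3–6 exons of
  100–300 bp), so distinct families share essentially no k-mers.
* **Isoforms** are exon subsets; the first isoform is always the full chain,
  additional isoforms are random non-empty subsets in exon order. Every
  isoform therefore shares at least one exon with its family's full
  isoform — the canonical-plus-skipping structure that exercises dynamic
  representation updates.
* **Reads** copy a uniformly chosen isoform, are truncated with probability
  0.2 by up to 30% from either end (RNA degradation, incomplete cDNA), and
  are reverse-complemented with probability 0.5.
* **Qualities and errors** follow a two-state segmental model: long
  high-quality runs (mean 80 bp around Q28) alternate with short low-quality
  stretches (mean 12 bp around Q6), mimicking the within-read error
  heterogeneity of nanopore data. For a target error rate both state means
  are shifted by a closed-form Phred offset so the expected per-base error
  equals the configured rate, and each base is then corrupted with
  probability exactly $10^{-q/10}$ (substitution/insertion/deletion split
  0.5/0.2/0.3). Quality strings are therefore consistent with the injected
  error process by construction. `errorRate = 0` emits clean reads at a
  constant Q40.

What the generator does *not* emulate: homopolymer-biased or signal-level
error profiles, reverse-transcription artifacts, artificial concatamers,
expression-level imbalance between isoforms, and shared exons *between*
families. Tests passing on this generator demonstrate the algorithmic
properties (quality gating, dynamic updates, merging, strand handling) under
realistic error statistics; they do not certify clustering quality on any
particular real dataset.

The segmental quality model matters for realism: with independent per-base
qualities at a 5% mean error, a 13-mer with all bases clean enough to pass
$T_1 = 0.95$ would be vanishingly rare and the quality gate would starve.
Real long reads — and this generator — concentrate errors in bursts, leaving
long clean runs that supply HCS.

## Validation strategy and problem sizes

The test suite checks every operation against an independent oracle: a naive
per-window scan for minimizer generation (exhaustive agreement over random
reads up to 60 bp, `k` ≤ 7, `w` ≤ 9, 10⁴ instances), brute-force pair
counting and direct entropy evaluation for all metrics (exhaustive over all
partition pairs for n ≤ 5 and all partitions of n = 6–8 against fixed
references), and straight-line replays of the greedy assignment and merge
sweep rules on hand-traced and random fixtures. End-to-end, the pipeline
must recover 10 simulated families of 50 reads exactly (ARI = 1) in the
error-free setting and with ARI ≥ 0.95 at 5% error with merging enabled;
a static-representation ablation must fail to chain overlapping isoforms
that the dynamic update chains into one cluster. These problem sizes keep
the whole suite under a minute while the properties they check are
size-independent.

## A worked example

```{r example}
sim <- simulateReads(simConfig(nFamilies = 4, readsPerFamily = 25,
                               errorRate = 0.05, seed = 42))
cl <- runPipeline(sim$reads,
                  config = clusterConfig("ont", postCluster = TRUE),
                  quiet = TRUE)
cl

truth <- sim$truth$family[match(names(readAssignments(cl)),
                                sim$truth$read_id)]
c(ari = adjustedRandIndex(readAssignments(cl), truth),
  v = vMeasure(readAssignments(cl), truth))
```

## Known limitations

* Single-threaded by design; the greedy pass is order-dependent, so a
  parallel variant would not be guaranteed to reproduce the same clustering.
* All reads and seed structures are held in memory; the sorted-order spill
  file (`spillTo`) re-streams reads but sorting itself is in-memory. This is
  adequate at the scales an R session handles; datasets of tens of millions
  of reads call for the compiled implementations this package's algorithm
  family comes from.
* Very high error rates (≥ 10%) starve the HCS gate at the default `t1`;
  lowering `t1` trades precision for recall there.
* The evaluator consumes an externally produced class TSV; constructing
  ground truth by genome alignment is out of scope.
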