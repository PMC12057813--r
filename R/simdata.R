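# Synthetic long-read transcriptome generator. Families are independent
# random exon chains; isoforms are exon subsets; reads are isoform copies
# with optional truncation, strand flips and quality-driven error injection.
# Qualities follow a two-state segmental model (long high-quality runs broken
# by short low-quality stretches), which is what makes quality-gated seed
# selection behave as it does on real long reads: errors concentrate in the
# low-quality stretches and leave long clean runs that yield high-confidence
# seeds even at several percent mean error.

.LN10_10 <- log(10) / 10

#' @keywords internal
#' @noRd
.lognormalErrorMean <- function(qMean, qSd) {
  # E[10^(-q/10)] for q ~ Normal(qMean, qSd^2)
  exp(-qMean * .LN10_10 + 0.5 * qSd^2 * .LN10_10^2)
}

#' Synthetic-data configuration
#'
#' Assembles and validates the parameters of [simulateReads()]. Defaults
#' describe a desk-scale ONT-like benchmark: 10 disjoint gene families, 50
#' reads each, 3-6 exons of 100-300 bp per family, 2-4 isoforms per family
#' (the first isoform is always the full exon chain, so every isoform shares
#' at least one exon with it), reads truncated with probability 0.2 by up to
#' 30% from either end, and both strand orientations.
#'
#' The quality model is two-state: high-quality segments (mean length
#' `segHigh` bp, Phred about `qHigh`) alternate with low-quality segments
#' (mean length `segLow` bp, Phred about `qLow`). For `errorRate > 0` both
#' state means are shifted by a closed-form Phred offset so that the expected
#' per-base error probability equals `errorRate`; errors are then injected
#' per base with probability exactly `10^(-q/10)`, so quality strings are
#' consistent with the injected error process by construction.
#' `errorRate = 0` emits error-free reads at constant Q40.
#'
#' @param nFamilies number of gene families.
#' @param readsPerFamily reads per family (single value or `c(min, max)`).
#' @param exonsPerFamily `c(min, max)` exon count per family.
#' @param exonLength `c(min, max)` exon length, bp.
#' @param isoformsPerFamily `c(min, max)` isoforms per family; must not
#'   exceed the number of non-empty exon subsets.
#' @param errorRate target mean per-base error probability in \[0, 0.2\].
#' @param errorSplit probabilities of substitution/insertion/deletion given
#'   an error; must sum to 1.
#' @param truncationProb probability a read is truncated.
#' @param truncationMax maximum truncated fraction of the read.
#' @param reverseStrandProb probability a read is emitted reverse-complemented.
#' @param qHigh,qSdHigh,qLow,qSdLow Phred mean and sd of the two quality states.
#' @param segHigh,segLow mean segment lengths (bp) of the two states.
#' @param seed RNG seed; the whole simulation is reproducible from it.
#' @return a validated `simConfig` list.
#' @export
simConfig <- function(nFamilies = 10L, readsPerFamily = 50L,
                      exonsPerFamily = c(3L, 6L), exonLength = c(100L, 300L),
                      isoformsPerFamily = c(2L, 4L),
                      errorRate = 0,
                      errorSplit = c(sub = 0.5, ins = 0.2, del = 0.3),
                      truncationProb = 0.2, truncationMax = 0.3,
                      reverseStrandProb = 0.5,
                      qHigh = 28, qSdHigh = 3, qLow = 6, qSdLow = 1.5,
                      segHigh = 80, segLow = 12,
                      seed = 1L) {
  rng <- function(v) if (length(v) == 1L) c(v, v) else sort(v[1:2])
  cfg <- list(nFamilies = as.integer(nFamilies),
              readsPerFamily = rng(as.integer(readsPerFamily)),
              exonsPerFamily = rng(as.integer(exonsPerFamily)),
              exonLength = rng(as.integer(exonLength)),
              isoformsPerFamily = rng(as.integer(isoformsPerFamily)),
              errorRate = errorRate, errorSplit = errorSplit,
              truncationProb = truncationProb, truncationMax = truncationMax,
              reverseStrandProb = reverseStrandProb,
              qHigh = qHigh, qSdHigh = qSdHigh, qLow = qLow, qSdLow = qSdLow,
              segHigh = segHigh, segLow = segLow, seed = as.integer(seed))
  probs <- c(cfg$errorRate, cfg$errorSplit, cfg$truncationProb,
             cfg$truncationMax, cfg$reverseStrandProb)
  if (any(probs < 0) || any(probs > 1))
    stop("all probabilities and fractions must lie in [0, 1]")
  if (abs(sum(cfg$errorSplit) - 1) > 1e-9)
    stop("errorSplit must sum to 1")
  if (cfg$nFamilies < 1L || any(cfg$exonLength < 1L) ||
      any(cfg$exonsPerFamily < 1L) || any(cfg$readsPerFamily < 1L))
    stop("counts and lengths must be positive")
  if (cfg$isoformsPerFamily[2] > 2^cfg$exonsPerFamily[1] - 1)
    stop("infeasible config: more isoforms requested than non-empty exon subsets")
  class(cfg) <- "simConfig"
  cfg
}

#' @keywords internal
#' @noRd
.sampleRange <- function(r) {
  # uniform integer in [r[1], r[2]]; safe when the range collapses
  r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L
}

#' @keywords internal
#' @noRd
.randomSeq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' @keywords internal
#' @noRd
.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' @keywords internal
#' @noRd
.segmentalQualities <- function(len, cfg, shift) {
  # alternate high/low quality runs with geometric lengths; start state drawn
  # by stationary occupancy
  q <- numeric(0)
  high <- runif(1) < cfg$segHigh / (cfg$segHigh + cfg$segLow)
  while (length(q) < len) {
    runLen <- 1L + rgeom(1L, 1 / (if (high) cfg$segHigh else cfg$segLow))
    mu <- (if (high) cfg$qHigh else cfg$qLow) - shift
    sdv <- if (high) cfg$qSdHigh else cfg$qSdLow
    q <- c(q, rnorm(runLen, mu, sdv))
    high <- !high
  }
  pmin(pmax(round(q[seq_len(len)]), 2), 41)
}

#' Simulate long transcriptomic reads with ground truth
#'
#' Generates gene families (random exon chains), isoforms (exon subsets,
#' always including the full chain), and reads (isoform copies with optional
#' truncation, strand flips and quality-driven substitution/indel errors).
#' See [simConfig()] for the generative model and its parameters.
#'
#' @param config a [simConfig()] object (or arguments forwarded to it via
#'   `...`).
#' @param ... used to build a config when `config` is missing.
#' @return list with elements `reads` (a
#'   [Biostrings::QualityScaledDNAStringSet] named by read id), `truth` (a
#'   `data.frame`: `read_id`, `family`, `isoform`, `strand`, `n_errors`,
#'   `template_length`) and `config`. Fully reproducible from `config$seed`;
#'   the caller's RNG state is preserved.
#' @examples
#' sim <- simulateReads(simConfig(nFamilies = 2, readsPerFamily = 3, seed = 7))
#' sim$reads
#' head(sim$truth)
#' @export
simulateReads <- function(config = simConfig(...), ...) {
  stopifnot(inherits(config, "simConfig"))
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  # closed-form Phred offset so the expected per-base error hits errorRate
  shift <- 0
  if (config$errorRate > 0) {
    fHigh <- config$segHigh / (config$segHigh + config$segLow)
    base <- fHigh * .lognormalErrorMean(config$qHigh, config$qSdHigh) +
      (1 - fHigh) * .lognormalErrorMean(config$qLow, config$qSdLow)
    shift <- 10 * log10(config$errorRate / base)
  }

  # families and isoforms
  isoforms <- list()  # per family: list of isoform sequences
  for (f in seq_len(config$nFamilies)) {
    nEx <- .sampleRange(config$exonsPerFamily)
    exons <- vapply(seq_len(nEx), function(i)
      .randomSeq(.sampleRange(config$exonLength)), "")
    nIso <- .sampleRange(config$isoformsPerFamily)
    subsets <- list(seq_len(nEx))  # isoform 1: the full exon chain
    while (length(subsets) < nIso) {
      keep <- which(runif(nEx) < 0.6)
      if (!length(keep)) next
      if (any(vapply(subsets, identical, TRUE, y = keep))) next
      subsets <- c(subsets, list(keep))
    }
    isoforms[[f]] <- lapply(subsets, function(s) paste(exons[s], collapse = ""))
  }

  ids <- character(0); seqs <- character(0); quals <- character(0)
  fam <- integer(0); iso <- integer(0); strand <- character(0)
  nErr <- integer(0); tmplLen <- integer(0)
  bases <- c("A", "C", "G", "T")
  readNo <- 0L
  for (f in seq_len(config$nFamilies)) {
    nReads <- .sampleRange(config$readsPerFamily)
    for (r in seq_len(nReads)) {
      readNo <- readNo + 1L
      i <- sample(length(isoforms[[f]]), 1L)
      tmpl <- isoforms[[f]][[i]]
      # truncation: clip a uniform fraction from the 5' or 3' end
      if (runif(1) < config$truncationProb) {
        cut <- floor(nchar(tmpl) * runif(1, 0, config$truncationMax))
        if (nchar(tmpl) - cut >= 50L) {
          tmpl <- if (runif(1) < 0.5) substring(tmpl, cut + 1L)
                  else substring(tmpl, 1L, nchar(tmpl) - cut)
        }
      }
      len <- nchar(tmpl)
      if (config$errorRate == 0) {
        q <- rep(40L, len)
        outSeq <- strsplit(tmpl, "")[[1]]
        outQ <- q
        errors <- 0L
      } else {
        q <- .segmentalQualities(len, config, shift)
        tmplChars <- strsplit(tmpl, "")[[1]]
        pErr <- 10^(-q / 10)
        isErr <- runif(len) < pErr
        errors <- sum(isErr)
        etype <- character(len)
        etype[isErr] <- sample(names(config$errorSplit), sum(isErr),
                               replace = TRUE, prob = config$errorSplit)
        chars <- tmplChars
        subs <- which(etype == "sub")
        if (length(subs)) {
          # substitute by rotating 1-3 steps through the alphabet
          off <- sample(1:3, length(subs), replace = TRUE)
          chars[subs] <- bases[(match(chars[subs], bases) - 1L + off) %% 4L + 1L]
        }
        times <- rep(1L, len)
        times[etype == "del"] <- 0L
        times[etype == "ins"] <- 2L
        outSeq <- rep(chars, times)
        outQ <- rep(q, times)
        insPos <- which(etype == "ins")
        if (length(insPos))  # second copy of an "ins" position is the insert
          outSeq[cumsum(times)[insPos]] <- sample(bases, length(insPos),
                                                  replace = TRUE)
      }
      seqOut <- paste(outSeq, collapse = "")
      qOut <- intToUtf8(outQ + 33L)
      flip <- runif(1) < config$reverseStrandProb
      if (flip) {
        seqOut <- .revcomp(seqOut)
        qOut <- paste(rev(strsplit(qOut, "")[[1]]), collapse = "")
      }
      ids <- c(ids, sprintf("read_%05d", readNo))
      seqs <- c(seqs, seqOut); quals <- c(quals, qOut)
      fam <- c(fam, f); iso <- c(iso, i)
      strand <- c(strand, if (flip) "-" else "+")
      nErr <- c(nErr, errors); tmplLen <- c(tmplLen, len)
    }
  }
  reads <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(seqs, ids)),
    Biostrings::PhredQuality(setNames(quals, ids)))
  truth <- data.frame(read_id = ids, family = fam, isoform = iso,
                      strand = strand, n_errors = nErr,
                      template_length = tmplLen)
  list(reads = reads, truth = truth, config = config)
}

#' Write a simulation to FASTQ plus a ground-truth TSV
#'
#' @param sim result of [simulateReads()].
#' @param fastq output FASTQ path (plain text, Phred+33).
#' @param truthTsv output TSV path (`read_id<TAB>family`), directly
#'   consumable as the class file of [evaluateClustering()].
#' @return invisibly, the two paths.
#' @export
writeSimulatedReads <- function(sim, fastq, truthTsv = NULL) {
  rt <- .readTable(sim$reads)
  .writeFastqLines(rt$id, rt$sequence, rt$quality, fastq)
  if (!is.null(truthTsv))
    write.table(sim$truth[, c("read_id", "family")], truthTsv,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(c(fastq = fastq, truth = truthTsv))
}
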