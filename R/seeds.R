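#' Convert Phred quality scores to correct-call probabilities
#'
#' A Phred score `q` encodes a base-call error probability `10^(-q/10)`; the
#' probability that the base was called correctly is therefore
#' `p = 1 - 10^(-q/10)`. Fractional scores are allowed (average error rates
#' are often quoted via a non-integer mean Q).
#'
#' @param q numeric vector of Phred scores, each in \[0, 93\].
#' @return numeric vector of correct-call probabilities in \[0, 1).
#' @examples
#' phredToProb(c(0, 10, 20))   # 0, 0.9, 0.99
#' 100 * (1 - phredToProb(13.5))  # mean error rate (%) at Q = 13.5
#' @export
phredToProb <- function(q) {
  if (!is.numeric(q) || anyNA(q) || any(q < 0) || any(q > 93))
    stop("Phred scores must be numeric values in [0, 93]")
  1 - 10^(-q / 10)
}

#' Decode a Phred+33 quality string
#'
#' @param quality a single FASTQ quality string (Phred+33 / Sanger offset).
#' @return integer vector of Phred scores, one per character.
#' @examples
#' decodeQuality("II5!")  # 40 40 20 0
#' @export
decodeQuality <- function(quality) {
  stopifnot(is.character(quality), length(quality) == 1L)
  q <- utf8ToInt(quality) - 33L
  if (length(q) && (min(q) < 0L || max(q) > 93L))
    stop("quality string contains characters outside the Phred+33 range")
  q
}

#' Seed confidence: probability that a k-mer is entirely correctly called
#'
#' The confidence of a seed spanning `k` bases is the product of the
#' per-base correct-call probabilities over those bases. A seed is a
#' high-confidence seed (HCS) when its confidence strictly exceeds the
#' threshold `t1`.
#'
#' @param q numeric vector of Phred scores covering exactly the k bases of
#'   one seed.
#' @return the product of `phredToProb(q)`, a probability in \[0, 1).
#' @examples
#' seedConfidence(c(10, 10, 10))  # 0.9^3 = 0.729
#' @export
seedConfidence <- function(q) {
  prod(phredToProb(q))
}

#' Hash k-mers into seed values
#'
#' Maps k-mers to numeric seed values inducing a total ordering. The default
#' `"hash"` ordering applies a 64-bit avalanche mixing function (splitmix64
#' finalizer) to the 2-bit encoding of the k-mer and masks the result to 53
#' bits so values are exactly representable as R doubles. The
#' `"lexicographic"` ordering returns the 2-bit encoding itself
#' (`A < C < G < T`), which makes minimizer choices predictable in tests and
#' examples.
#'
#' @param kmers character vector of k-mers (one `k` throughout, `k <= 26`).
#' @param ordering `"hash"` or `"lexicographic"`.
#' @return numeric vector of seed values; `NA` for k-mers containing
#'   non-ACGT characters (callers skip such k-mers).
#' @examples
#' kmerHash("AC", ordering = "lexicographic")  # 1 (0b0001)
#' kmerHash(c("AAA", "AAC", "TTT"), ordering = "lexicographic")
#' @export
kmerHash <- function(kmers, ordering = c("hash", "lexicographic")) {
  ordering <- match.arg(ordering)
  .kmer_hash_cpp(as.character(kmers), ordering == "lexicographic")
}

#' Generate (canonical) minimizer seeds for one read
#'
#' Scans the read with windows of `w` consecutive k-mer start positions and
#' emits, per window, the k-mer with the smallest seed value (leftmost
#' position on ties); a minimizer shared by overlapping windows is emitted
#' once. With `canonical = TRUE` each position's value is the smaller of the
#' forward k-mer's and its reverse complement's hash, so the seed set is
#' strand-symmetric. k-mers containing non-ACGT characters are excluded from
#' candidacy; a window with no valid k-mer emits nothing. Reads with fewer
#' than `w` k-mer positions are scanned as a single window.
#'
#' Seed confidence is computed from the forward-read quality substring at the
#' seed position (qualities are per sequenced base, whichever strand's k-mer
#' won the canonical comparison).
#'
#' @param sequence a single DNA sequence string.
#' @param quality matching Phred+33 quality string, or `NULL` to skip
#'   confidences.
#' @param k,w seed length and window size.
#' @param canonical use canonical (strand-symmetric) seed values.
#' @param ordering seed ordering, see [kmerHash()].
#' @return a `data.frame` with columns `position` (1-based seed start),
#'   `value` (numeric seed value) and `confidence` (probability the seed is
#'   fully correctly called; `NA` when `quality` is `NULL`), sorted by
#'   position. Zero rows when the read is shorter than `k`.
#' @examples
#' minimizerSeeds("ACGTACGT", NULL, k = 3, w = 2,
#'                canonical = FALSE, ordering = "lexicographic")
#' @export
minimizerSeeds <- function(sequence, quality = NULL, k, w, canonical = TRUE,
                           ordering = c("hash", "lexicographic")) {
  ordering <- match.arg(ordering)
  stopifnot(length(sequence) == 1L, k >= 1L, k <= 26L, w >= 1L)
  res <- .minimizer_scan_cpp(as.character(sequence), as.integer(k),
                             as.integer(w), isTRUE(canonical),
                             ordering == "lexicographic")
  pos <- res$position
  conf <- rep(NA_real_, length(pos))
  if (!is.null(quality) && length(pos)) {
    q <- decodeQuality(quality)
    if (length(q) != nchar(sequence))
      stop("sequence and quality must have equal length")
    # product of per-base probabilities via cumulative log sums; q = 0 gives
    # p = 0, clamped to a finite log so spans after it stay well-defined
    lp <- log(phredToProb(q))
    lp[lp == -Inf] <- -800
    cl <- c(0, cumsum(lp))
    conf <- exp(cl[pos + k] - cl[pos])
  }
  data.frame(position = pos, value = res$value, confidence = conf)
}

#' Distinct high-confidence seed values
#'
#' @param seeds a seed `data.frame` from [minimizerSeeds()].
#' @param t1 confidence threshold; a seed qualifies iff `confidence > t1`
#'   (strict).
#' @return numeric vector of distinct seed values among the qualifying seeds,
#'   in order of first occurrence.
#' @export
highConfidenceSeeds <- function(seeds, t1) {
  stopifnot(is.data.frame(seeds), t1 >= 0, t1 <= 1)
  keep <- !is.na(seeds$confidence) & seeds$confidence > t1
  unique(seeds$value[keep])
}
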