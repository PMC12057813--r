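#' @keywords internal
#' @noRd
.readTable <- function(reads) {
  if (methods::is(reads, "QualityScaledDNAStringSet")) {
    ids <- names(reads)
    if (is.null(ids)) ids <- as.character(seq_along(reads))
    return(list(id = ids,
                sequence = as.character(reads),
                quality = as.character(Biostrings::quality(reads))))
  }
  if (is.data.frame(reads)) {
    stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
    return(list(id = as.character(reads$id),
                sequence = as.character(reads$sequence),
                quality = as.character(reads$quality)))
  }
  if (is.list(reads) && all(c("id", "sequence", "quality") %in% names(reads)))
    return(reads)
  stop("reads must be a QualityScaledDNAStringSet or a data.frame with ",
       "columns id, sequence, quality")
}

#' Sort reads by decreasing high-confidence seed count
#'
#' Computes the (canonical) minimizer seeds of every read, classifies them
#' against the `t1` threshold, and orders the reads by decreasing number of
#' high-confidence seeds (HCS). The count is over HCS seed positions. The
#' sort is stable: reads with equal HCS counts keep their input order, which
#' makes the downstream clustering deterministic. Ordering reads so that the
#' seed-richest come first lets the most informative reads found the clusters.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet] (e.g. from
#'   [readFastq()]) or a `data.frame` with columns `id`, `sequence`,
#'   `quality`.
#' @param config a [ClusterConfig-class].
#' @param spillTo optional path; when given, the reads are also written in
#'   sorted order as a plain FASTQ file (the re-streamable intermediate
#'   store).
#' @return a `SortedReadStream`: a list with elements `id`, `sequence`,
#'   `quality` (character vectors in sorted order), `seeds` (list of seed
#'   `data.frame`s), `hcs` (list of distinct HCS value vectors) and
#'   `hcsCount` (integer vector, non-increasing).
#' @seealso [greedyCluster()]
#' @export
sortReadsBySeeds <- function(reads, config, spillTo = NULL) {
  rt <- .readTable(reads)
  n <- length(rt$id)
  seeds <- vector("list", n)
  hcs <- vector("list", n)
  hcsCount <- integer(n)
  for (i in seq_len(n)) {
    s <- minimizerSeeds(rt$sequence[i], rt$quality[i], k = config@k,
                        w = config@w, canonical = config@canonical,
                        ordering = config@ordering)
    seeds[[i]] <- s
    hcs[[i]] <- highConfidenceSeeds(s, config@t1)
    hcsCount[i] <- sum(!is.na(s$confidence) & s$confidence > config@t1)
  }
  ord <- order(-hcsCount)  # radix: stable, ties keep input order
  stream <- list(id = rt$id[ord], sequence = rt$sequence[ord],
                 quality = rt$quality[ord], seeds = seeds[ord],
                 hcs = hcs[ord], hcsCount = hcsCount[ord])
  if (!is.null(spillTo))
    .writeFastqLines(stream$id, stream$sequence, stream$quality, spillTo)
  stream
}
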