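#' @keywords internal
#' @noRd
.writeFastqLines <- function(ids, seqs, quals, path) {
  con <- file(path, "wb")  # binary mode: byte-identical output across platforms
  on.exit(close(con))
  if (length(ids)) {
    rec <- paste0("@", ids, "\n", seqs, "\n+\n", quals)
    writeLines(rec, con, sep = "\n")
  }
  invisible(path)
}

#' Read a FASTQ file into a QualityScaledDNAStringSet
#'
#' Parses 4-line FASTQ records with Phred+33 (Sanger) qualities via
#' Biostrings; gzip-compressed input is decoded transparently. When the file
#' contains malformed records (e.g. sequence and quality of different
#' lengths), a line-level recovery pass keeps the well-formed records and
#' skips the rest with a warning; the skip count is available as
#' `attr(x, "skipped")`.
#'
#' @param path path to a FASTQ or FASTQ.gz file.
#' @return a named [Biostrings::QualityScaledDNAStringSet].
#' @export
readFastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  # cheap framing scan first: Biostrings pads mismatched quality strings
  # silently, so malformed records must be caught at the line level
  lines <- readLines(path)
  n4 <- length(lines) %/% 4L
  framed <- length(lines) == 4L * n4 && n4 > 0L &&
    all(startsWith(lines[seq(1L, by = 4L, length.out = n4)], "@")) &&
    all(startsWith(lines[seq(3L, by = 4L, length.out = n4)], "+")) &&
    all(nchar(lines[seq(2L, by = 4L, length.out = n4)]) ==
        nchar(lines[seq(4L, by = 4L, length.out = n4)]))
  if (framed) {
    reads <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    # FASTQ headers may carry a description after the id
    names(reads) <- sub("\\s.*$", "", names(reads))
    attr(reads, "skipped") <- 0L
    return(reads)
  }
  # recovery: scan 4-line records, keep the well-formed ones
  skipped <- 0L
  ids <- character(0); seqs <- character(0); quals <- character(0)
  i <- 1L
  while (i <= length(lines)) {
    if (i + 3L > length(lines)) { skipped <- skipped + 1L; break }  # truncated
    hd <- lines[i]; sq <- lines[i + 1L]; pl <- lines[i + 2L]; ql <- lines[i + 3L]
    ok <- startsWith(hd, "@") && startsWith(pl, "+") &&
      nchar(sq) == nchar(ql) && nchar(sq) > 0L &&
      !grepl("[^ACGTNacgtn]", sq)
    if (ok) {
      ids <- c(ids, sub("^@", "", sub("\\s.*$", "", hd)))
      seqs <- c(seqs, sq); quals <- c(quals, ql)
    } else {
      skipped <- skipped + 1L
    }
    i <- i + 4L
  }
  if (skipped > 0L)
    warning(sprintf("skipped %d malformed FASTQ record(s) in %s",
                    skipped, path))
  reads <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(seqs, ids)),
    Biostrings::PhredQuality(stats::setNames(quals, ids)))
  attr(reads, "skipped") <- skipped
  reads
}

#' Write clustering outputs: assignment TSV and per-cluster FASTQ files
#'
#' Writes `final_clusters.tsv` (`cluster_id<TAB>read_id`, one line per read)
#' plus one FASTQ file per cluster with at least `minSize` member reads.
#' Output cluster ids are renumbered `0..C-1` by decreasing member count,
#' ties broken by creation order, so id 0 is always the largest cluster.
#'
#' @param clustering a [ReadClustering-class].
#' @param reads the reads that were clustered (any input accepted by
#'   [sortReadsBySeeds()]); needed for the per-cluster FASTQ files. `NULL`
#'   writes the TSV only.
#' @param outfolder output directory, created if missing.
#' @param minSize minimum member count for a per-cluster FASTQ file; `NULL`
#'   takes `minOutputSize` from the clustering's config.
#' @return invisibly, the path of the TSV file.
#' @export
writeClusterOutputs <- function(clustering, reads = NULL, outfolder,
                                minSize = NULL) {
  if (is.null(minSize)) minSize <- clustering@config@minOutputSize
  dir.create(outfolder, showWarnings = FALSE, recursive = TRUE)
  sizes <- lengths(clustering@members)
  ord <- order(-sizes)                     # stable: ties keep creation order
  newId <- integer(length(sizes))
  newId[ord] <- seq_along(ord) - 1L        # 0-based output ids
  tsv <- file.path(outfolder, "final_clusters.tsv")
  con <- file(tsv, "wb")
  for (rank in seq_along(ord)) {
    cid <- ord[rank]
    writeLines(paste0(rank - 1L, "\t", clustering@members[[cid]]), con,
               sep = "\n")
  }
  close(con)
  if (!is.null(reads)) {
    rt <- .readTable(reads)
    for (cid in which(sizes >= minSize)) {
      idx <- match(clustering@members[[cid]], rt$id)
      .writeFastqLines(rt$id[idx], rt$sequence[idx], rt$quality[idx],
                       file.path(outfolder, sprintf("%d.fastq", newId[cid])))
    }
  }
  invisible(tsv)
}

#' Run the full clustering pipeline
#'
#' Sorting (by decreasing high-confidence seed count), single-pass greedy
#' clustering, optional iterative cluster merging, and file output, executed
#' single-threaded with per-stage wall times and counts reported via
#' `message()`.
#'
#' @param input a FASTQ path, a [Biostrings::QualityScaledDNAStringSet], or
#'   a `data.frame` with columns `id`, `sequence`, `quality`.
#' @param outfolder output directory for `final_clusters.tsv` and
#'   per-cluster FASTQ files; `NULL` skips file output.
#' @param config a [ClusterConfig-class]; built from `mode` and `...` when
#'   missing.
#' @param mode,... forwarded to [clusterConfig()] when `config` is missing
#'   (e.g. `postCluster = TRUE` to activate merging).
#' @param quiet suppress progress messages.
#' @return the final [ReadClustering-class], invisibly when `outfolder` is
#'   given.
#' @examples
#' sim <- simulateReads(simConfig(nFamilies = 3, readsPerFamily = 5, seed = 2))
#' cl <- runPipeline(sim$reads, config = clusterConfig("ont"), quiet = TRUE)
#' nClusters(cl)
#' @export
runPipeline <- function(input, outfolder = NULL, config = NULL,
                        mode = "ont", ..., quiet = FALSE) {
  if (is.null(config)) config <- clusterConfig(mode, ...)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  reads <- if (is.character(input) && length(input) == 1L) readFastq(input)
           else input
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  stream <- sortReadsBySeeds(reads, config)
  timings$sorting <- tic() - t0
  say("sorted %d reads [%.2fs]", length(stream$id), timings$sorting)
  t0 <- tic()
  clustering <- greedyCluster(stream, config)
  timings$clustering <- tic() - t0
  say("greedy clustering: %d clusters from %d reads [%.2fs]",
      nClusters(clustering), length(stream$id), timings$clustering)
  if (config@postCluster) {
    t0 <- tic()
    before <- nClusters(clustering)
    clustering <- mergeUntilFixpoint(clustering)
    timings$merging <- tic() - t0
    say("cluster merging: %d -> %d clusters in %d sweep(s) [%.2fs]",
        before, nClusters(clustering), clustering@stats$mergeSweeps,
        timings$merging)
  }
  clustering@stats$timings <- timings
  if (!is.null(outfolder)) {
    t0 <- tic()
    tsv <- writeClusterOutputs(clustering, reads, outfolder)
    clustering@stats$timings$output <- tic() - t0
    say("wrote %s [%.2fs]", tsv, clustering@stats$timings$output)
    return(invisible(clustering))
  }
  clustering
}
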