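# Iterative cluster merging. Cluster "size" here is the number of
# high-confidence seed values in the representation (not the member count).
# Within a sweep, visit order, eligibility and target choice are computed
# from a sweep-start snapshot of the representations; merges mutate the live
# state. If a chosen target was itself absorbed earlier in the sweep, the
# merge is postponed to the next sweep (chain postponement).

#' One merging sweep over all clusters
#'
#' Visits clusters in ascending order of representation size (ties: ascending
#' cluster id). For a visited cluster `c1`, eligible targets are clusters
#' with a strictly larger representation, or an equal-sized one with a
#' smaller id. Among eligible targets, the one sharing the most HCS values
#' with `c1` (ties: smallest id) is chosen; if the shared fraction relative
#' to `|hcs(c1)|` strictly exceeds `t3`, `c1` is merged into it: members are
#' appended and the target's representation becomes the union. Clusters with
#' empty representations are never merged.
#'
#' @param clustering a [ReadClustering-class].
#' @param t3 merge threshold; `NULL` takes it from the clustering's config.
#' @return list with elements `clustering` (after the sweep, absorbed
#'   clusters dropped and ids compacted in creation order) and `merged`
#'   (number of merges performed).
#' @seealso [mergeUntilFixpoint()]
#' @export
mergeClustersPass <- function(clustering, t3 = NULL) {
  if (is.null(t3)) t3 <- clustering@config@t3
  members <- clustering@members
  reps <- clustering@representations
  nc <- length(reps)
  reps0 <- reps                      # sweep-start snapshot
  sizes0 <- lengths(reps0)
  index0 <- .buildSeedIndex(reps0)
  absorbed <- logical(nc)
  merged <- 0L
  for (c1 in order(sizes0)) {        # stable: ties in ascending id order
    if (absorbed[c1] || sizes0[c1] == 0L) next
    counts <- sharedSeedCounts(reps0[[c1]], index0)
    if (!length(counts)) next
    ids <- as.integer(names(counts))
    eligible <- sizes0[ids] > sizes0[c1] | (sizes0[ids] == sizes0[c1] & ids < c1)
    ids <- ids[eligible]
    counts <- counts[eligible]
    if (!length(ids)) next
    best <- max(counts)
    if (best / sizes0[c1] <= t3) next          # strict: fraction must exceed t3
    c2 <- min(ids[counts == best])
    if (absorbed[c2]) next                     # chain postponement
    members[[c2]] <- c(members[[c2]], members[[c1]])
    reps[[c2]] <- unique(c(reps[[c2]], reps[[c1]]))
    absorbed[c1] <- TRUE
    merged <- merged + 1L
  }
  keep <- which(!absorbed)
  newId <- integer(nc)
  newId[keep] <- seq_along(keep)
  # remap assignments through the absorption chain (one level per sweep)
  target <- seq_len(nc)
  for (c1 in which(absorbed)) {
    # find where c1's members went: they were appended to exactly one keeper
    for (c2 in keep) {
      if (all(clustering@members[[c1]] %in% members[[c2]])) { target[c1] <- c2; break }
    }
  }
  assignments <- newId[target[clustering@assignments]]
  names(assignments) <- names(clustering@assignments)
  out <- new("ReadClustering",
    assignments = assignments,
    members = members[keep],
    representations = reps[keep],
    config = clustering@config,
    stats = clustering@stats)
  list(clustering = out, merged = merged)
}

#' Merge clusters until no merge occurs
#'
#' Repeats [mergeClustersPass()] until a sweep performs zero merges. Each
#' sweep recomputes sizes and representations, so merges postponed by the
#' chain rule happen in later sweeps. Terminates because every merge strictly
#' decreases the cluster count. Operates on representations and member id
#' lists only; read sequences are never touched, so peak memory is unaffected
#' by merging.
#'
#' @param clustering a [ReadClustering-class].
#' @param t3 merge threshold; `NULL` takes it from the clustering's config.
#' @return the merged [ReadClustering-class]; `stats$mergeSweeps` counts all
#'   sweeps including the final zero-merge one, and `stats$nClustersInitial`
#'   keeps the pre-merge count.
#' @export
mergeUntilFixpoint <- function(clustering, t3 = NULL) {
  initial <- nClusters(clustering)
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    res <- mergeClustersPass(clustering, t3)
    clustering <- res$clustering
    if (res$merged == 0L) break
    stopifnot(sweeps <= initial)  # termination guard
  }
  clustering@stats$mergeSweeps <- sweeps
  clustering@stats$nClustersInitial <- initial
  clustering
}
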