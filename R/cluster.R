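# Greedy single-pass clustering with dynamically updated cluster
# representations. The seed index is an environment used as a hash table:
# seed value (formatted as an integer string) -> integer vector of cluster
# ids whose representation contains that value.

.seedKey <- function(values) sprintf("%.0f", values)

#' @keywords internal
#' @noRd
.newSeedIndex <- function() new.env(hash = TRUE, parent = emptyenv())

#' @keywords internal
#' @noRd
.indexAdd <- function(index, values, clusterId) {
  for (key in .seedKey(values)) {
    cur <- index[[key]]
    if (is.null(cur)) {
      index[[key]] <- clusterId
    } else if (!clusterId %in% cur) {
      index[[key]] <- c(cur, clusterId)
    }
  }
  invisible(NULL)
}

#' @keywords internal
#' @noRd
.buildSeedIndex <- function(representations) {
  index <- .newSeedIndex()
  for (cid in seq_along(representations))
    .indexAdd(index, representations[[cid]], cid)
  index
}

#' Count seeds shared between a read and each indexed cluster
#'
#' For every cluster whose representation contains at least one of the given
#' seed values, returns the number of distinct values shared. Clusters
#' sharing nothing are absent from the result.
#'
#' @param seedValues numeric vector of distinct seed values (typically all
#'   distinct seeds of a read).
#' @param index a seed index environment mapping seed values to cluster ids
#'   (built internally by [greedyCluster()]; exposed for testing and
#'   inspection).
#' @return named integer vector: names are cluster ids, values are shared
#'   distinct-seed counts.
#' @export
sharedSeedCounts <- function(seedValues, index) {
  hits <- unlist(mget(.seedKey(seedValues), envir = index,
                      ifnotfound = list(NULL)), use.names = FALSE)
  if (is.null(hits) || !length(hits)) return(integer(0))
  table(hits) |> c()  # named integer counts, names = cluster ids
}

#' Greedy clustering of a sorted read stream
#'
#' Streams once over the sorted reads. The first read founds a cluster whose
#' representation is its set of high-confidence seeds (HCS). Each following
#' read is compared, through the seed index, against all clusters sharing at
#' least one seed value with it: let `D` be the number of distinct seed
#' values of the read (all seeds, not only HCS) and `S` the largest shared
#' count. If `S / D >= t2` the read joins the cluster with the most shared
#' seeds (ties: smallest cluster id) and any of its HCS missing from that
#' cluster's representation are added (the dynamic update); otherwise it
#' founds a new cluster represented by its HCS. Reads with no seeds found
#' their own (never-attracting) cluster and are counted in
#' `stats$zeroSeedReads`.
#'
#' @param stream a `SortedReadStream` from [sortReadsBySeeds()].
#' @param config a [ClusterConfig-class]; `t2` is the join threshold.
#' @param dynamic logical; `FALSE` freezes every representation at the
#'   founder's HCS (the static-representation ablation; clustering quality
#'   drops on chained isoforms, which is the point of the comparison).
#' @return a [ReadClustering-class] with clusters numbered in creation order.
#' @export
greedyCluster <- function(stream, config, dynamic = TRUE) {
  n <- length(stream$id)
  assignments <- integer(n)
  members <- list()
  reps <- list()
  index <- .newSeedIndex()
  zeroSeed <- 0L
  for (i in seq_len(n)) {
    vals <- unique(stream$seeds[[i]]$value)
    hcs <- stream$hcs[[i]]
    D <- length(vals)
    joined <- 0L
    if (D > 0L) {
      counts <- sharedSeedCounts(vals, index)
      if (length(counts)) {
        best <- max(counts)
        if (best / D >= config@t2) {
          cand <- as.integer(names(counts)[counts == best])
          joined <- min(cand)  # tie-break: oldest cluster
        }
      }
    } else {
      zeroSeed <- zeroSeed + 1L
    }
    if (joined > 0L) {
      assignments[i] <- joined
      members[[joined]] <- c(members[[joined]], stream$id[i])
      if (dynamic && length(hcs)) {
        inRep <- vapply(.seedKey(hcs),
                        function(key) joined %in% index[[key]], logical(1))
        if (any(!inRep)) {
          newVals <- hcs[!inRep]
          reps[[joined]] <- c(reps[[joined]], newVals)
          .indexAdd(index, newVals, joined)
        }
      }
    } else {
      cid <- length(members) + 1L
      assignments[i] <- cid
      members[[cid]] <- stream$id[i]
      reps[[cid]] <- hcs
      .indexAdd(index, hcs, cid)
    }
  }
  names(assignments) <- stream$id
  new("ReadClustering",
    assignments = assignments, members = members, representations = reps,
    config = config,
    stats = list(nReads = n, zeroSeedReads = zeroSeed,
                 nClustersInitial = length(members), mergeSweeps = 0L,
                 seedIndex = index))
}

#' Number of clusters
#' @param x a [ReadClustering-class]
#' @return integer cluster count
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname nClusters
#' @export
setMethod("nClusters", "ReadClustering", function(x) length(x@members))

#' Cluster sizes (member counts), in creation order
#' @param x a [ReadClustering-class]
#' @return integer vector of member counts
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname clusterSizes
#' @export
setMethod("clusterSizes", "ReadClustering", function(x) lengths(x@members))

#' Member read ids per cluster
#' @param x a [ReadClustering-class]
#' @return list of character vectors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname clusterMembers
#' @export
setMethod("clusterMembers", "ReadClustering", function(x) x@members)

#' High-confidence seed representations per cluster
#' @param x a [ReadClustering-class]
#' @return list of numeric seed-value vectors
#' @export
setGeneric("clusterRepresentations",
           function(x) standardGeneric("clusterRepresentations"))

#' @rdname clusterRepresentations
#' @export
setMethod("clusterRepresentations", "ReadClustering",
          function(x) x@representations)

#' Read-to-cluster assignments
#' @param x a [ReadClustering-class]
#' @return named integer vector (read id -> cluster id, creation order)
#' @export
setGeneric("readAssignments", function(x) standardGeneric("readAssignments"))

#' @rdname readAssignments
#' @export
setMethod("readAssignments", "ReadClustering", function(x) x@assignments)

#' @describeIn greedyCluster display a clustering result
#' @param object a `ReadClustering`
#' @export
setMethod("show", "ReadClustering", function(object) {
  sz <- lengths(object@members)
  cat(sprintf(
    "ReadClustering: %d reads in %d clusters (%d non-singleton)\n",
    length(object@assignments), length(sz), sum(sz > 1L)))
  if (length(sz))
    cat(sprintf("  largest cluster: %d reads; %d singleton cluster(s)\n",
                max(sz), sum(sz == 1L)))
  if (!is.null(object@stats$mergeSweeps) && object@stats$mergeSweeps > 0L)
    cat(sprintf("  merging: %d -> %d clusters in %d sweep(s)\n",
                object@stats$nClustersInitial, length(sz),
                object@stats$mergeSweeps))
  invisible(NULL)
})

#' @describeIn greedyCluster assignments as a two-column data.frame
#' @param x a `ReadClustering`
#' @param ... ignored
#' @export
setMethod("as.data.frame", "ReadClustering", function(x, ...) {
  data.frame(read_id = names(x@assignments),
             cluster_id = unname(x@assignments))
})
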