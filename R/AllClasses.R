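#' Clustering configuration
#'
#' Holds every tunable of the pipeline: seeding parameters (`k`, `w`,
#' `canonical`, seed ordering), the high-confidence threshold `t1`, the
#' greedy-assignment threshold `t2` and the cluster-merging threshold `t3`.
#'
#' Technology presets follow the published calibration: ONT uses
#' `k = 13, w = 21, t1 = 0.95, t3 = 0.5`; PacBio uses
#' `k = 15, w = 51, t1 = 0.98, t3 = 0.8`; `t2 = 0.5` for both.
#'
#' @slot mode character, one of `"ont"`, `"pacbio"`, `"custom"`.
#' @slot k integer k-mer length (2-bit packed internally, so `k <= 26`).
#' @slot w integer window size: number of consecutive k-mer start positions
#'   per window. Both even and odd values are accepted.
#' @slot canonical logical; use canonical (strand-symmetric) minimizers.
#' @slot t1 numeric in \[0,1\]; a seed is high-confidence iff its probability
#'   of being fully correctly base-called exceeds `t1` (strict).
#' @slot t2 numeric in \[0,1\]; a read joins a cluster iff the fraction of its
#'   distinct seed values found in the cluster representation is `>= t2`.
#' @slot t3 numeric in \[0,1\]; a cluster merges into a larger one iff the
#'   shared fraction of its HCS exceeds `t3` (strict).
#' @slot postCluster logical; run iterative cluster merging after the greedy
#'   pass.
#' @slot minOutputSize integer; only clusters with at least this many member
#'   reads get a per-cluster FASTQ file.
#' @slot ordering character, `"hash"` (default, avalanche hash) or
#'   `"lexicographic"` (2-bit encoding; intended for tests and didactics).
#'
#' @seealso [clusterConfig()]
#' @exportClass ClusterConfig
setClass("ClusterConfig",
  representation(
    mode = "character",
    k = "integer",
    w = "integer",
    canonical = "logical",
    t1 = "numeric",
    t2 = "numeric",
    t3 = "numeric",
    postCluster = "logical",
    minOutputSize = "integer",
    ordering = "character"
  )
)

setValidity("ClusterConfig", function(object) {
  msg <- character()
  if (!object@mode %in% c("ont", "pacbio", "custom"))
    msg <- c(msg, "mode must be 'ont', 'pacbio' or 'custom'")
  if (object@k < 1L || object@k > 26L)
    msg <- c(msg, "k must be in [1, 26]")
  if (object@w < 1L) msg <- c(msg, "w must be >= 1")
  for (nm in c("t1", "t2", "t3")) {
    v <- slot(object, nm)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must be a single value in [0,1]", nm))
  }
  if (!object@ordering %in% c("hash", "lexicographic"))
    msg <- c(msg, "ordering must be 'hash' or 'lexicographic'")
  if (object@minOutputSize < 1L) msg <- c(msg, "minOutputSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Result of a clustering run
#'
#' Container returned by [greedyCluster()], [mergeUntilFixpoint()] and
#' [runPipeline()]. Cluster ids are integers in creation order (1-based
#' internally); output renumbering by size happens only in
#' [writeClusterOutputs()].
#'
#' @slot assignments named integer vector, read id -> cluster id.
#' @slot members list of character vectors of read ids, one per cluster.
#' @slot representations list of numeric vectors: the distinct
#'   high-confidence seed values representing each cluster.
#' @slot config the [ClusterConfig-class] used.
#' @slot stats list of run statistics (read counts, cluster counts before and
#'   after merging, merge sweeps, per-stage timings).
#'
#' @seealso [nClusters()], [clusterSizes()], [clusterMembers()],
#'   [clusterRepresentations()], [readAssignments()]
#' @exportClass ReadClustering
setClass("ReadClustering",
  representation(
    assignments = "integer",
    members = "list",
    representations = "list",
    config = "ClusterConfig",
    stats = "list"
  )
)

setValidity("ReadClustering", function(object) {
  msg <- character()
  if (length(object@members) != length(object@representations))
    msg <- c(msg, "members and representations must have equal length")
  if (length(object@assignments) &&
      sum(lengths(object@members)) != length(object@assignments))
    msg <- c(msg, "cluster sizes must sum to the number of assigned reads")
  if (length(msg)) msg else TRUE
})
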