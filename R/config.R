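#' Build a clustering configuration
#'
#' Creates a [ClusterConfig-class], starting from a technology preset and
#' applying any explicit overrides. The presets are the published
#' calibration for each technology:
#'
#' | mode   | k  | w  | t1   | t2  | t3  |
#' |--------|----|----|------|-----|-----|
#' | ont    | 13 | 21 | 0.95 | 0.5 | 0.5 |
#' | pacbio | 15 | 51 | 0.98 | 0.5 | 0.8 |
#'
#' `mode = "custom"` applies no preset; all parameters then fall back to the
#' defaults shown in the argument list unless given.
#'
#' @param mode `"ont"`, `"pacbio"` or `"custom"`.
#' @param k,w seed length and window size (number of k-mer start positions
#'   per window).
#' @param t1 high-confidence seed threshold (strict `>`).
#' @param t2 greedy join threshold on the fraction of a read's distinct seed
#'   values shared with a cluster representation (inclusive `>=`).
#' @param t3 merge threshold on the fraction of a cluster's HCS shared with a
#'   larger cluster (strict `>`).
#' @param canonical use canonical (strand-symmetric) minimizers.
#' @param postCluster run the iterative merging pass.
#' @param minOutputSize minimum member count for a per-cluster FASTQ file.
#' @param ordering `"hash"` or `"lexicographic"` seed ordering.
#' @return a validated [ClusterConfig-class] object.
#' @examples
#' clusterConfig("ont")
#' clusterConfig("pacbio", postCluster = TRUE)
#' clusterConfig("custom", k = 9, w = 5, t1 = 0.9)
#' @export
clusterConfig <- function(mode = c("ont", "pacbio", "custom"),
                          k = NULL, w = NULL, t1 = NULL, t2 = NULL, t3 = NULL,
                          canonical = TRUE, postCluster = FALSE,
                          minOutputSize = 1L,
                          ordering = c("hash", "lexicographic")) {
  mode <- match.arg(mode)
  ordering <- match.arg(ordering)
  preset <- switch(mode,
    ont    = list(k = 13L, w = 21L, t1 = 0.95, t2 = 0.5, t3 = 0.5),
    pacbio = list(k = 15L, w = 51L, t1 = 0.98, t2 = 0.5, t3 = 0.8),
    custom = list(k = 13L, w = 21L, t1 = 0.95, t2 = 0.5, t3 = 0.5)
  )
  pick <- function(user, def) if (is.null(user)) def else user
  new("ClusterConfig",
    mode = mode,
    k = as.integer(pick(k, preset$k)),
    w = as.integer(pick(w, preset$w)),
    canonical = isTRUE(canonical),
    t1 = as.numeric(pick(t1, preset$t1)),
    t2 = as.numeric(pick(t2, preset$t2)),
    t3 = as.numeric(pick(t3, preset$t3)),
    postCluster = isTRUE(postCluster),
    minOutputSize = as.integer(minOutputSize),
    ordering = ordering
  )
}

#' @describeIn clusterConfig display a configuration
#' @param object a `ClusterConfig`
#' @export
setMethod("show", "ClusterConfig", function(object) {
  cat(sprintf(
    "ClusterConfig [%s]: k=%d w=%d %s ordering=%s\n  t1=%.3g t2=%.3g t3=%.3g  postCluster=%s\n",
    object@mode, object@k, object@w,
    if (object@canonical) "canonical" else "forward-strand",
    object@ordering, object@t1, object@t2, object@t3,
    if (object@postCluster) "on" else "off"
  ))
  invisible(NULL)
})
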