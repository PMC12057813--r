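# External clustering-evaluation metrics over two labelings of the same
# reads: X = predicted cluster ids, Y = ground-truth class ids. Labels are
# opaque; only equality matters. Entropies use natural logarithms (the
# measures are entropy ratios, so the base cancels).

#' @keywords internal
#' @noRd
.checkLabeling <- function(x, y, minN = 1L) {
  if (length(x) != length(y))
    stop("labelings must have equal length")
  if (length(x) < minN)
    stop(sprintf("labelings must contain at least %d elements", minN))
  invisible(NULL)
}

#' @keywords internal
#' @noRd
.entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' @keywords internal
#' @noRd
.conditionalEntropy <- function(tab) {
  # H(col | row) for a contingency table of counts
  n <- sum(tab)
  rows <- rowSums(tab)
  h <- 0
  for (i in seq_len(nrow(tab))) {
    nz <- tab[i, ][tab[i, ] > 0]
    if (length(nz)) h <- h - sum(nz / n * log(nz / rows[i]))
  }
  h
}

#' Homogeneity of a clustering against ground-truth classes
#'
#' `h = 1 - H(Y|X) / H(Y)`: a clustering is perfectly homogeneous when every
#' cluster contains reads of a single class; mixing classes in one cluster
#' (over-clustering) is penalized. When `H(Y) = 0` (a single class) the
#' clustering is trivially homogeneous and 1 is returned.
#'
#' @param x cluster ids per read.
#' @param y class ids per read (same length).
#' @return homogeneity in \[0, 1\].
#' @seealso [completeness()], [vMeasure()], [adjustedRandIndex()]
#' @export
homogeneity <- function(x, y) {
  .checkLabeling(x, y)
  hy <- .entropy(table(y))
  if (hy == 0) return(1)
  tab <- table(x, y)
  1 - .conditionalEntropy(tab) / hy
}

#' Completeness of a clustering against ground-truth classes
#'
#' `c = 1 - H(X|Y) / H(X)`: a clustering is complete when all reads of each
#' class land in a single cluster; splitting a class across clusters
#' (under-clustering) is penalized. When `H(X) = 0` (a single cluster) 1 is
#' returned.
#'
#' @inheritParams homogeneity
#' @return completeness in \[0, 1\].
#' @export
completeness <- function(x, y) {
  .checkLabeling(x, y)
  hx <- .entropy(table(x))
  if (hx == 0) return(1)
  tab <- table(y, x)
  1 - .conditionalEntropy(tab) / hx
}

#' V-measure: harmonic mean of homogeneity and completeness
#'
#' @inheritParams homogeneity
#' @return `2hc / (h + c)`, or 0 when `h + c = 0`.
#' @export
vMeasure <- function(x, y) {
  h <- homogeneity(x, y)
  cc <- completeness(x, y)
  if (h + cc == 0) return(0)
  2 * h * cc / (h + cc)
}

#' Rand index: fraction of read pairs on which two partitions agree
#'
#' A pair is in agreement when both partitions place the two reads together,
#' or both place them apart: `RI = (TP + TN) / (TP + FP + TN + FN)` over all
#' `choose(n, 2)` pairs.
#'
#' @inheritParams homogeneity
#' @return Rand index in \[0, 1\]. Errors when `n < 2` (no pairs exist).
#' @export
randIndex <- function(x, y) {
  .checkLabeling(x, y, minN = 2L)
  tab <- table(x, y)
  n <- sum(tab)
  tp <- sum(choose(tab, 2))
  togetherX <- sum(choose(rowSums(tab), 2))
  togetherY <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  tn <- total - togetherX - togetherY + tp
  (tp + tn) / total
}

#' Adjusted Rand index (chance-corrected pair agreement)
#'
#' Computed from the contingency table as
#' `ARI = (sum_ij C(n_ij,2) - t3) / (0.5 (t1 + t2) - t3)` with
#' `t1 = sum_i C(n_i.,2)`, `t2 = sum_j C(n_.j,2)` and
#' `t3 = 2 t1 t2 / (n (n-1))`. Identical partitions score 1; uniformly
#' random labelings score about 0. In the degenerate case of a zero
#' denominator (e.g. both partitions all-singletons, or both one block)
#' returns 1 if the partitions are identical and 0 otherwise.
#'
#' @inheritParams homogeneity
#' @return ARI in \[-1, 1\]. Errors when `n < 2`.
#' @export
adjustedRandIndex <- function(x, y) {
  .checkLabeling(x, y, minN = 2L)
  tab <- table(x, y)
  n <- sum(tab)
  sumIJ <- sum(choose(tab, 2))
  t1 <- sum(choose(rowSums(tab), 2))
  t2 <- sum(choose(colSums(tab), 2))
  t3 <- 2 * t1 * t2 / (n * (n - 1))
  den <- (t1 + t2) / 2 - t3
  if (den == 0) {
    identical_partition <- all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
    return(if (identical_partition) 1 else 0)
  }
  (sumIJ - t3) / den
}

#' Summarize a clustering: singleton structure and read coverage
#'
#' Reports non-singleton (NS, more than one read) and singleton (S) cluster
#' counts and the percentage of reads placed in clusters of at least
#' `minSize` reads. Downstream steps (error correction, isoform
#' reconstruction) typically need a minimum of 3-5 reads per cluster, so
#' `minSize` is exposed; the default 2 reports the fraction in non-trivial
#' (non-singleton) clusters.
#'
#' @param x cluster ids per read.
#' @param minSize minimum cluster size counted as "kept".
#' @return list with `nClusters`, `nonSingletonClusters`,
#'   `singletonClusters`, `pctReadsInClusters` (percentage of reads in
#'   clusters of size >= `minSize`).
#' @export
clusteringSummary <- function(x, minSize = 2L) {
  sizes <- as.integer(table(x))
  list(
    nClusters = length(sizes),
    nonSingletonClusters = sum(sizes > 1L),
    singletonClusters = sum(sizes == 1L),
    pctReadsInClusters = 100 * sum(sizes[sizes >= minSize]) / max(1L, sum(sizes))
  )
}

#' Evaluate a clustering TSV against a ground-truth class TSV
#'
#' Reads a cluster assignment table and a class (ground truth) table, joins
#' them on read id, and computes homogeneity, completeness, V-measure, Rand
#' index, adjusted Rand index and summary counts. By default the clusters
#' file is `cluster_id<TAB>read_id` (the layout written by
#' [writeClusterOutputs()]) and the classes file is
#' `read_id<TAB>class_id`; use `clusterColumns`/`classColumns` for other
#' layouts.
#'
#' Reads present in the clustering but absent from the class file
#' ("unclassified", e.g. unalignable reads in a reference-guided truth) are
#' handled per `unclassified`: `"singleton"` (default) gives each its own
#' unique class so all reads enter the metrics; `"exclude"` drops them.
#'
#' @param clustersFile path to the clustering TSV (no header).
#' @param classesFile path to the class TSV (no header).
#' @param unclassified `"singleton"` or `"exclude"`.
#' @param clusterColumns,classColumns two-element character vectors naming
#'   the columns in file order; must contain `"read_id"` and `"cluster_id"`
#'   / `"class_id"`.
#' @return list with `h`, `c`, `v`, `ri`, `ari`, `n`, plus cluster and class
#'   summaries from [clusteringSummary()].
#' @export
evaluateClustering <- function(clustersFile, classesFile,
                               unclassified = c("singleton", "exclude"),
                               clusterColumns = c("cluster_id", "read_id"),
                               classColumns = c("read_id", "class_id")) {
  unclassified <- match.arg(unclassified)
  clu <- read.delim(clustersFile, header = FALSE, colClasses = "character")
  names(clu) <- clusterColumns
  cla <- read.delim(classesFile, header = FALSE, colClasses = "character")
  names(cla) <- classColumns
  y <- cla$class_id[match(clu$read_id, cla$read_id)]
  x <- clu$cluster_id
  miss <- is.na(y)
  if (any(miss)) {
    if (unclassified == "exclude") {
      x <- x[!miss]
      y <- y[!miss]
    } else {
      y[miss] <- paste0("unclassified_", seq_len(sum(miss)))
    }
  }
  list(
    h = homogeneity(x, y),
    c = completeness(x, y),
    v = vMeasure(x, y),
    ri = randIndex(x, y),
    ari = adjustedRandIndex(x, y),
    n = length(x),
    clusters = clusteringSummary(x),
    classes = clusteringSummary(y)
  )
}
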