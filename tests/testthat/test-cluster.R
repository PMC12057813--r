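# Perfect-quality helper: all seeds are HCS, so representations equal seed sets
perfectStream <- function(seqs, config, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%d", seq_along(seqs))
  quals <- vapply(seqs, function(s) strrep("I", nchar(s)), "")
  makeStream(ids, seqs, quals, config)
}

cfg95 <- clusterConfig("custom", k = 5, w = 3, t1 = 0.9, t2 = 0.5)

test_that("shared seed counts match brute-force set intersections", {
  set.seed(8)
  reps <- list(
    as.numeric(c(10, 11, 12, 13)),
    as.numeric(c(12, 13, 14)),
    as.numeric(c(20, 21)))
  index <- seedclust:::.buildSeedIndex(reps)
  query <- c(11, 12, 13, 20, 99)
  counts <- sharedSeedCounts(query, index)
  brute <- vapply(reps, function(r) length(intersect(query, r)), 0L)
  expect_equal(unname(counts[as.character(1:3)]), brute)
  # disjoint query: empty result
  expect_length(sharedSeedCounts(c(500, 501), index), 0)
})

test_that("first read founds a cluster; an identical read joins it", {
  set.seed(9)
  r <- randomDNA(80)
  stream <- perfectStream(c(r, r), cfg95)
  cl <- greedyCluster(stream, cfg95)
  expect_equal(nClusters(cl), 1L)
  expect_equal(unname(readAssignments(cl)), c(1L, 1L))
  # representation equals the founder's HCS (set-wise)
  expect_setequal(clusterRepresentations(cl)[[1]], stream$hcs[[1]])
  # exact duplicates join even at t2 = 1 (inclusive threshold)
  cfg1 <- clusterConfig("custom", k = 5, w = 3, t1 = 0.9, t2 = 1.0)
  cl1 <- greedyCluster(stream, cfg1)
  expect_equal(nClusters(cl1), 1L)
})

test_that("disjoint families give separate clusters; zero-seed reads are flagged", {
  set.seed(10)
  a <- randomDNA(120); b <- randomDNA(120)
  stream <- perfectStream(c(a, a, b, b), cfg95)
  cl <- greedyCluster(stream, cfg95)
  expect_equal(nClusters(cl), 2L)
  # a read with no seeds founds its own, never-attracting cluster
  stream2 <- perfectStream(c(a, "ACG", a), cfg95)  # shorter than k: no seeds
  cl2 <- greedyCluster(stream2, cfg95)
  expect_equal(cl2@stats$zeroSeedReads, 1L)
  expect_equal(nClusters(cl2), 2L)
  expect_equal(sum(lengths(clusterRepresentations(cl2)) == 0), 1L)
})

test_that("greedy assignment matches the straight-line replay oracle", {
  # 5-read, two-family fixture with overlapping isoforms
  set.seed(12)
  e1 <- randomDNA(150); e2 <- randomDNA(150); e3 <- randomDNA(150)
  f2 <- randomDNA(300)
  seqs <- c(paste0(e1, e2, e3), paste0(e1, e2), paste0(e2, e3), f2, f2)
  stream <- perfectStream(seqs, cfg95)
  # stream must be sorted by decreasing HCS count for the contract
  ord <- order(-stream$hcsCount)
  stream <- lapply(stream, function(el) el[ord])
  got <- readAssignments(greedyCluster(stream, cfg95))
  exp <- replayGreedy(stream, t2 = 0.5)
  expect_equal(got, exp)
  # and on larger random synthetic data
  sim <- simulateReads(simConfig(nFamilies = 4, readsPerFamily = 8,
                                 errorRate = 0.05, seed = 33))
  cfg <- clusterConfig("ont")
  stream <- sortReadsBySeeds(sim$reads, cfg)
  got <- readAssignments(greedyCluster(stream, cfg))
  exp <- replayGreedy(stream, t2 = cfg@t2)
  expect_equal(got, exp)
})

test_that("clustering is a partition and representations are member-HCS unions", {
  sim <- simulateReads(simConfig(nFamilies = 3, readsPerFamily = 10,
                                 errorRate = 0.03, seed = 14))
  cfg <- clusterConfig("ont")
  stream <- sortReadsBySeeds(sim$reads, cfg)
  cl <- greedyCluster(stream, cfg)
  # partition: every read assigned exactly once; sizes sum to n
  expect_setequal(names(readAssignments(cl)), stream$id)
  expect_equal(sum(clusterSizes(cl)), length(stream$id))
  # representation-union invariant
  hcsOf <- setNames(stream$hcs, stream$id)
  for (cid in seq_len(nClusters(cl))) {
    expected <- unique(unlist(hcsOf[clusterMembers(cl)[[cid]]]))
    expect_setequal(clusterRepresentations(cl)[[cid]],
                    if (is.null(expected)) numeric(0) else expected)
  }
  # index consistency: rebuilding the seed index from the final
  # representations reproduces the live index
  live <- cl@stats$seedIndex
  rebuilt <- seedclust:::.buildSeedIndex(clusterRepresentations(cl))
  expect_setequal(ls(live), ls(rebuilt))
  for (key in ls(rebuilt))
    expect_setequal(live[[key]], rebuilt[[key]])
})

test_that("dynamic representation updates chain overlapping isoforms into one cluster", {
  fx <- chainOverlapReads()
  cfg <- clusterConfig("custom", k = 9, w = 5, t1 = 0.9, t2 = 0.5)
  stream <- makeStream(fx$ids, fx$seqs, fx$quals, cfg)
  dynamic <- greedyCluster(stream, cfg, dynamic = TRUE)
  static <- greedyCluster(stream, cfg, dynamic = FALSE)
  expect_equal(nClusters(dynamic), 1L)
  expect_gte(nClusters(static), 2L)
})

test_that("clustering is deterministic", {
  sim <- simulateReads(simConfig(nFamilies = 3, readsPerFamily = 8,
                                 errorRate = 0.05, seed = 18))
  cfg <- clusterConfig("ont")
  run <- function() {
    readAssignments(greedyCluster(sortReadsBySeeds(sim$reads, cfg), cfg))
  }
  expect_identical(run(), run())
})
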