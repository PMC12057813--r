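test_that("Phred conversion follows p = 1 - 10^(-q/10) and validates range", {
  expect_equal(phredToProb(0), 0)
  expect_equal(phredToProb(10), 0.9)
  expect_equal(phredToProb(20), 0.99)
  # fractional scores: mean error rate of 4.5% at Q = 13.5
  expect_equal(phredToProb(13.5), 1 - 10^(-1.35))
  expect_error(phredToProb(-1), "Phred")
  expect_error(phredToProb(94), "Phred")
  expect_equal(decodeQuality("II5!"), c(40L, 40L, 20L, 0L))
})

test_that("seed confidence is the product of per-base probabilities", {
  expect_equal(seedConfidence(c(10, 10, 10)), 0.729)
  # limit case: at q = 93 the confidence is 1 - 2e-9.3 + 1e-18.6, i.e. within
  # about 1e-9 of 1
  expect_equal(seedConfidence(c(93, 93)), (1 - 10^-9.3)^2)
  expect_lt(abs(seedConfidence(c(93, 93)) - 1), 1.1e-9)
  # HCS classification is strict
  expect_false(0.729 > 0.95)
  expect_true(0.97 > 0.95)
})

test_that("k-mer hashing is deterministic and lexicographic mode orders A<C<G<T", {
  kmers <- c("AAA", "AAC", "TTT")
  expect_identical(kmerHash(kmers), kmerHash(kmers))
  lex <- kmerHash(kmers, "lexicographic")
  expect_true(lex[1] < lex[2] && lex[2] < lex[3])
  expect_equal(kmerHash("AC", "lexicographic"), 1)  # 0b0001
  expect_true(is.na(kmerHash("ANA")))
  expect_true(is.na(kmerHash("ANA", "lexicographic")))
  # hash values fit exactly in doubles (53-bit mask)
  v <- kmerHash(c("ACGTACGTACGTA", "TTTTTTTTTTTTT"))
  expect_true(all(v == floor(v) & v < 2^53))
})

test_that("minimizer scan matches the brute-force window oracle on fixtures", {
  # identity ordering, r = "ACGTACGT", k = 3, w = 2: frozen from the oracle
  got <- minimizerSeeds("ACGTACGT", NULL, k = 3, w = 2, canonical = FALSE,
                        ordering = "lexicographic")
  expect_equal(got$position, c(1L, 2L, 3L, 5L))
  expect_equal(got$value, c(6, 27, 44, 6))
  exp <- oracleMinimizers("ACGTACGT", 3, 2, FALSE, "lexicographic")
  expect_equal(got$position, exp$position)
  expect_equal(got$value, exp$value)
  # canonical, r = "TTTTAAAA": oracle agreement
  got <- minimizerSeeds("TTTTAAAA", NULL, k = 3, w = 2, canonical = TRUE,
                        ordering = "lexicographic")
  exp <- oracleMinimizers("TTTTAAAA", 3, 2, TRUE, "lexicographic")
  expect_equal(got$position, exp$position)
  expect_equal(got$value, exp$value)
})

test_that("degenerate window settings behave as specified", {
  # w = 1: every k-mer is a seed
  got <- minimizerSeeds("ACGTACGT", NULL, k = 3, w = 1, canonical = FALSE)
  expect_equal(got$position, 1:6)
  # read of length k: exactly one seed at position 1
  got <- minimizerSeeds("ACGT", NULL, k = 4, w = 5, canonical = FALSE)
  expect_equal(nrow(got), 1L)
  expect_equal(got$position, 1L)
  # read of length k, canonical: value is hash of smaller of r / revcomp(r)
  got <- minimizerSeeds("TTTT", NULL, k = 4, w = 1, canonical = TRUE,
                        ordering = "lexicographic")
  expect_equal(got$value, kmerHash("AAAA", "lexicographic"))
  # read shorter than k: empty seed list
  expect_equal(nrow(minimizerSeeds("ACG", NULL, k = 5, w = 2)), 0L)
  # window with no valid k-mer emits nothing
  expect_equal(nrow(minimizerSeeds("ACGNNNNNGT", NULL, k = 5, w = 3)), 0L)
})

test_that("minimizer scan agrees with the oracle on random instances", {
  set.seed(11)
  for (rep in 1:300) {
    len <- sample(1:60, 1)
    k <- sample(2:7, 1)
    w <- sample(1:9, 1)
    canonical <- rep %% 2 == 0
    ordering <- if (rep %% 3 == 0) "lexicographic" else "hash"
    r <- randomDNA(len, nProb = 0.05)
    got <- minimizerSeeds(r, NULL, k = k, w = w, canonical = canonical,
                          ordering = ordering)
    exp <- oracleMinimizers(r, k, w, canonical, ordering)
    expect_equal(got$position, exp$position,
                 info = sprintf("r=%s k=%d w=%d", r, k, w))
    expect_equal(got$value, exp$value)
  }
})

test_that("canonical seed values are strand-symmetric", {
  # The set of emitted canonical values is invariant under reverse
  # complementation. (The positional multiset is not exactly invariant: when
  # adjacent k-mers are each other's reverse complements their tied canonical
  # values collapse differently near read ends; downstream cluster
  # representations are sets, so set invariance is the operative property.)
  set.seed(3)
  for (rep in 1:40) {
    r <- randomDNA(sample(20:80, 1))
    q <- paste(sample(strsplit("!+5?I", "")[[1]], nchar(r), TRUE),
               collapse = "")
    fw <- minimizerSeeds(r, q, k = 5, w = 4, canonical = TRUE)
    rv <- minimizerSeeds(oracleRevcomp(r),
                         paste(rev(strsplit(q, "")[[1]]), collapse = ""),
                         k = 5, w = 4, canonical = TRUE)
    expect_setequal(fw$value, rv$value)
  }
})

test_that("confidence of a canonical seed uses the forward-strand qualities", {
  # TTTT's canonical value comes from the reverse complement AAAA, but the
  # confidence must be computed from the read's own quality characters
  q <- "I5+!"
  got <- minimizerSeeds("TTTT", q, k = 4, w = 1, canonical = TRUE)
  expect_equal(got$confidence, prod(phredToProb(decodeQuality(q))))
})

test_that("high-confidence seed selection is strict, monotone and bounded", {
  set.seed(5)
  r <- randomDNA(60)
  q <- paste(sample(strsplit("#+5?I", "")[[1]], 60, TRUE), collapse = "")
  seeds <- minimizerSeeds(r, q, k = 4, w = 3)
  # seed count bound: at most one seed per k-mer start position
  expect_lte(nrow(seeds), 60 - 4 + 1)
  # t1 = 0 keeps all distinct values (every confidence > 0 for q >= 1)
  expect_setequal(highConfidenceSeeds(seeds, 0), unique(seeds$value))
  # t1 = 1 keeps nothing (confidence < 1 always)
  expect_length(highConfidenceSeeds(seeds, 1), 0)
  # monotonicity: t1 <= t1' implies HCS(t1') subset of HCS(t1)
  ts <- sort(runif(5))
  for (i in seq_len(4)) {
    expect_true(all(highConfidenceSeeds(seeds, ts[i + 1]) %in%
                    highConfidenceSeeds(seeds, ts[i])))
  }
})

test_that("mixed-quality read keeps exactly the high-quality seeds", {
  # three seeds at fixed positions (w = 1, k = 3, non-overlapping qualities):
  # confidences recomputed by hand from the Phred string
  r <- "ACGTGA"
  q <- "III!!I"   # Q40 Q40 Q40 Q0 Q0 Q40
  seeds <- minimizerSeeds(r, q, k = 3, w = 1, canonical = FALSE)
  expect_equal(nrow(seeds), 4L)
  p40 <- 1 - 1e-4
  expect_equal(seeds$confidence[1], p40^3)          # positions 1-3: all Q40
  expect_equal(seeds$confidence[2], 0)              # contains a Q0 base
  hcs <- highConfidenceSeeds(seeds, 0.95)
  expect_equal(hcs, seeds$value[1])                 # only the clean seed
})
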