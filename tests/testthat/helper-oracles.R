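# Independent oracles: brute-force / straight-line implementations of the
# operations under test. They deliberately avoid the package's windowed scan,
# seed index and contingency-table code paths.

randomDNA <- function(len, nProb = 0) {
  alpha <- c("A", "C", "G", "T")
  s <- sample(alpha, len, replace = TRUE)
  if (nProb > 0) s[runif(len) < nProb] <- "N"
  paste(s, collapse = "")
}

oracleRevcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgtn", "TGCAtgcan", s), "")[[1]]),
        collapse = "")
}

# Naive per-window minimizer scan. Windows are w consecutive k-mer start
# positions (clamped to one window when fewer than w exist); smallest value
# wins, leftmost on ties; duplicate positions across windows reported once.
oracleMinimizers <- function(seq, k, w, canonical = FALSE,
                             ordering = "hash") {
  n <- nchar(seq)
  npos <- n - k + 1L
  empty <- data.frame(position = integer(0), value = numeric(0))
  if (npos < 1L) return(empty)
  kmers <- substring(seq, seq_len(npos), seq_len(npos) + k - 1L)
  vals <- kmerHash(kmers, ordering)
  if (canonical) {
    rcvals <- kmerHash(vapply(kmers, oracleRevcomp, ""), ordering)
    vals <- pmin(vals, rcvals)
  }
  ww <- min(w, npos)
  pos <- integer(0)
  for (s in seq_len(npos - ww + 1L)) {
    win <- s:(s + ww - 1L)
    v <- vals[win]
    if (all(is.na(v))) next
    p <- win[which.min(v)]  # which.min: leftmost on ties, skips NA
    pos <- c(pos, p)
  }
  pos <- unique(pos)
  data.frame(position = pos, value = vals[pos])
}

# All set partitions of n elements as label vectors (restricted growth
# strings); used for exhaustive metric checks.
allPartitions <- function(n) {
  out <- list()
  grow <- function(labels, maxLab) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible(NULL))
    }
    for (lab in seq_len(maxLab + 1L))
      grow(c(labels, lab), max(maxLab, lab))
    invisible(NULL)
  }
  grow(integer(0), 0L)
  out
}

# Pair-counting oracle: enumerate all unordered pairs and classify agreement.
oraclePairCounts <- function(x, y) {
  n <- length(x)
  a <- b <- cc <- d <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sx <- x[i] == x[j]
      sy <- y[i] == y[j]
      if (sx && sy) a <- a + 1L
      else if (sx && !sy) b <- b + 1L
      else if (!sx && sy) cc <- cc + 1L
      else d <- d + 1L
    }
  }
  list(a = a, b = b, c = cc, d = d)
}

oracleRandIndex <- function(x, y) {
  p <- oraclePairCounts(x, y)
  (p$a + p$d) / (p$a + p$b + p$c + p$d)
}

# ARI in its pair-counting form (equivalent to the contingency-table form):
# 2(ad - bc) / ((a+b)(b+d) + (a+c)(c+d))
oracleARI <- function(x, y) {
  p <- oraclePairCounts(x, y)
  den <- (p$a + p$b) * (p$b + p$d) + (p$a + p$c) * (p$c + p$d)
  if (den == 0)
    return(if (p$b == 0 && p$c == 0) 1 else 0)
  2 * (p$a * p$d - p$b * p$c) / den
}

# Direct-entropy oracle for homogeneity / completeness / V.
oracleEntropy <- function(labels) {
  p <- table(labels) / length(labels)
  -sum(p * log(p))
}

oracleCondEntropy <- function(target, given) {
  # H(target | given), by explicit conditioning
  h <- 0
  for (g in unique(given)) {
    sel <- given == g
    pg <- mean(sel)
    tt <- table(target[sel]) / sum(sel)
    h <- h - pg * sum(tt * log(tt))
  }
  h
}

oracleHCV <- function(x, y) {
  hy <- oracleEntropy(y)
  hx <- oracleEntropy(x)
  h <- if (hy == 0) 1 else 1 - oracleCondEntropy(y, x) / hy
  cc <- if (hx == 0) 1 else 1 - oracleCondEntropy(x, y) / hx
  v <- if (h + cc == 0) 0 else 2 * h * cc / (h + cc)
  list(h = h, c = cc, v = v)
}

# Straight-line replay of the greedy assignment rule, comparing each read
# exhaustively against every cluster representation (no seed index).
replayGreedy <- function(stream, t2, dynamic = TRUE) {
  reps <- list()
  assign <- integer(length(stream$id))
  for (i in seq_along(stream$id)) {
    vals <- unique(stream$seeds[[i]]$value)
    hcs <- stream$hcs[[i]]
    joined <- 0L
    if (length(vals) && length(reps)) {
      shared <- vapply(reps, function(r) length(intersect(vals, r)), 0L)
      best <- max(shared)
      if (best > 0 && best / length(vals) >= t2)
        joined <- which(shared == best)[1L]
    }
    if (joined > 0L) {
      assign[i] <- joined
      if (dynamic) reps[[joined]] <- union(reps[[joined]], hcs)
    } else {
      reps[[length(reps) + 1L]] <- hcs
      assign[i] <- length(reps)
    }
  }
  names(assign) <- stream$id
  assign
}

# Straight-line replay of one merge sweep (snapshot semantics, chain
# postponement), comparing clusters exhaustively.
replayMergeSweep <- function(reps, t3) {
  sizes <- lengths(reps)
  absorbed <- rep(FALSE, length(reps))
  into <- rep(NA_integer_, length(reps))
  live <- reps
  for (c1 in order(sizes)) {
    if (sizes[c1] == 0L) next
    shared <- vapply(seq_along(reps), function(c2) {
      if (c2 == c1) return(-1L)
      ok <- sizes[c2] > sizes[c1] || (sizes[c2] == sizes[c1] && c2 < c1)
      if (!ok) return(-1L)
      length(intersect(reps[[c1]], reps[[c2]]))
    }, 0L)
    if (max(shared) <= 0) next
    c2 <- which(shared == max(shared))[1L]
    if (max(shared) / sizes[c1] <= t3) next
    if (absorbed[c2]) next  # chain postponement
    live[[c2]] <- union(live[[c2]], live[[c1]])
    absorbed[c1] <- TRUE
    into[c1] <- c2
    merged <- TRUE
  }
  list(reps = live[!absorbed], absorbed = absorbed, into = into,
       merged = sum(absorbed))
}

# Build a minimal sorted-stream structure from raw reads (id/seq/qual),
# without the package's sorting (callers order them as needed).
makeStream <- function(ids, seqs, quals, config) {
  seeds <- lapply(seq_along(ids), function(i)
    minimizerSeeds(seqs[i], quals[i], k = config@k, w = config@w,
                   canonical = config@canonical, ordering = config@ordering))
  hcs <- lapply(seeds, highConfidenceSeeds, t1 = config@t1)
  list(id = ids, sequence = seqs, quality = quals, seeds = seeds, hcs = hcs,
       hcsCount = vapply(seeds, function(s)
         sum(!is.na(s$confidence) & s$confidence > config@t1), 0L))
}

# Chain-overlap isoform fixture: three reads A, B, C where A and B share a
# segment, B and C share another, and A and C share nothing. Exercises the
# dynamic representation update.
chainOverlapReads <- function(seed = 42) {
  set.seed(seed)
  s1 <- randomDNA(300); s2 <- randomDNA(400)
  s3 <- randomDNA(300); s4 <- randomDNA(200)
  seqs <- c(A = paste0(s1, s2), B = paste0(s2, s3), C = paste0(s3, s4))
  quals <- vapply(seqs, function(s) strrep("I", nchar(s)), "")
  list(ids = names(seqs), seqs = unname(seqs), quals = unname(quals))
}

# Four-cluster merge fixture with one postponed chain merge (see
# test-merge.R for the full hand replay).
mergeChainClustering <- function(t3 = 0.5) {
  reps <- list(
    as.numeric(1:10),                       # c1
    as.numeric(c(1:6, 11:14)),              # c2: overlaps c1 by 6
    as.numeric(c(1:3, 11:17)),              # c3: overlaps c2 by 7, c1 by 3
    as.numeric(101:120)                     # c4: disjoint, largest
  )
  members <- list("rA", "rB", "rC", "rD")
  assignments <- setNames(1:4, c("rA", "rB", "rC", "rD"))
  new("ReadClustering", assignments = assignments, members = members,
      representations = reps,
      config = clusterConfig("custom", t3 = t3),
      stats = list(nReads = 4L))
}
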