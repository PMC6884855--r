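test_that("p-distances use pairwise deletion of gaps and ambiguities", {
  a <- strrep("ACGT", 100)               # 400 nt
  expect_equal(pairwise_pdistance(a, a), 0)
  b <- substr(strrep("ACGT", 100), 1, 313)
  a313 <- substr(a, 1, 313)
  substr(b, 100, 100) <- "G"    # position 100 of the repeat is a T
  expect_equal(pairwise_pdistance(a313, b), 1 / 313)
  ## N at the only differing site: distance 0 over 312 compared sites
  bn <- b
  substr(bn, 100, 100) <- "N"
  expect_equal(pairwise_pdistance(a313, bn), 0)
  expect_error(pairwise_pdistance(strrep("N", 10), strrep("A", 10)),
               "no comparable sites")
  expect_error(pairwise_pdistance("ACGT", "ACG"), "equal length")
})

test_that("the distance matrix matches an independent oracle", {
  set.seed(71)
  base <- random_dna(1, 200)
  seqs <- vapply(1:8, function(i) {
    s <- base
    for (p in sample(200, 12)) {
      ch <- sample(c("A", "C", "G", "T", "N"), 1)
      substr(s, p, p) <- ch
    }
    s
  }, character(1))
  names(seqs) <- sprintf("s%02d", 1:8)
  dm <- pdistance_matrix(seqs, aligned = TRUE)
  expect_equal(unname(dm), unname(pdist_oracle(seqs)), tolerance = 1e-12)
  expect_true(isSymmetric(dm))
  expect_true(all(diag(dm) == 0))
})

test_that("objective clustering is single linkage with a strict threshold", {
  ids <- letters[1:3]
  mk <- function(v) {
    m <- matrix(0, 3, 3, dimnames = list(ids, ids))
    m[lower.tri(m)] <- v
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    m
  }
  ## all-zero distances: one cluster
  expect_length(cluster_otus(mk(c(0, 0, 0)), 0.03)$clusters, 1)
  ## chaining: a-b 2%, b-c 2%, a-c 4% at 3% -> one cluster
  chain <- mk(c(0.02, 0.04, 0.02))     # lower.tri order: (b,a),(c,a),(c,b)
  expect_length(cluster_otus(chain, 0.03)$clusters, 1)
  ## two tight blocks 10% apart split at 3%
  ids4 <- letters[1:4]
  m4 <- matrix(0.10, 4, 4, dimnames = list(ids4, ids4))
  m4[1, 2] <- m4[2, 1] <- 0.01
  m4[3, 4] <- m4[4, 3] <- 0.01
  diag(m4) <- 0
  p4 <- cluster_otus(m4, 0.03)
  expect_length(p4$clusters, 2)
  ## a pair at exactly the threshold is NOT merged
  m2 <- matrix(c(0, 0.03, 0.03, 0), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  expect_length(cluster_otus(m2, 0.03)$clusters, 2)
  expect_length(cluster_otus(m2, 0.0300001)$clusters, 1)
})

test_that("single linkage equals graph connected components on random matrices", {
  set.seed(72)
  for (rep in 1:8) {
    n <- sample(10:50, 1)
    d <- matrix(runif(n * n, 0, 0.1), n, n)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    dimnames(d) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
    for (t in c(0.02, 0.05)) {
      got <- cluster_otus(d, t)$membership
      want <- components_oracle(d, t)
      ## same partition up to label renaming
      expect_equal(unname(got[order(rownames(d))]),
                   match(want, unique(want))[order(rownames(d))])
    }
  }
})

test_that("raising the threshold never increases the cluster count", {
  set.seed(73)
  n <- 30
  d <- matrix(runif(n * n, 0, 0.08), n, n)
  d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  counts <- vapply(seq(0.005, 0.06, by = 0.005), function(t)
    length(cluster_otus(d, t)$clusters), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the match ratio counts identical clusters", {
  p_ab_c <- as_partition(c(a = 1, b = 1, c = 2))
  p_a_b_c <- as_partition(c(a = 1, b = 2, c = 3))
  mr <- match_ratio(p_ab_c, p_a_b_c)
  expect_equal(mr$n_match, 1)           # {c} is shared
  expect_equal(mr$ratio, 2 * 1 / (2 + 3))
  ## identical partitions
  expect_equal(match_ratio(p_ab_c, p_ab_c)$ratio, 1)
  ## completely crossing partitions share nothing
  p1 <- as_partition(c(a = 1, b = 1, c = 2, d = 2))
  p2 <- as_partition(c(a = 1, b = 2, c = 1, d = 2))
  expect_equal(match_ratio(p1, p2)$ratio, 0)
  ## symmetric, bounded
  expect_equal(match_ratio(p_a_b_c, p_ab_c)$ratio,
               match_ratio(p_ab_c, p_a_b_c)$ratio)
  expect_error(match_ratio(p_ab_c, as_partition(c(a = 1, z = 2))),
               "different specimen sets")
})

test_that("the congruence scan finds where incongruent clusters heal", {
  ids <- c("a", "b", "c")
  ## dm_a merges a,b below 2%; dm_b only below 3.5%
  mk <- function(ab) {
    m <- matrix(0.2, 3, 3, dimnames = list(ids, ids))
    m[1, 2] <- m[2, 1] <- ab
    diag(m) <- 0
    m
  }
  dm_a <- mk(0.019)
  dm_b <- mk(0.034)
  ## at 3% base threshold: {a,b} in A but {a},{b} in B
  scan <- congruence_threshold_scan(dm_a, dm_b, base_threshold = 0.03,
                                    thresholds = seq(0.01, 0.10, 0.001))
  expect_equal(nrow(scan), 1)
  expect_equal(scan$congruent_at, 0.035)
  ## congruent partitions produce an empty table
  empty <- congruence_threshold_scan(dm_a, dm_a, base_threshold = 0.03)
  expect_equal(nrow(empty), 0)
  ## clusters that never heal report NA
  dm_c <- mk(0.5)
  dm_c[1, 3] <- dm_c[3, 1] <- 0.011    # c joins a in B-space only
  never <- congruence_threshold_scan(mk(0.02), dm_c,
                                     base_threshold = 0.03,
                                     thresholds = seq(0.01, 0.10, 0.01))
  expect_true(any(is.na(never$congruent_at)))
})

test_that("Chao1 uses the classical formula with a bias-corrected fallback", {
  ## from explicit counts
  expect_equal(chao1(list(S_obs = 10, F1 = 4, F2 = 2))$estimate, 14)
  expect_equal(chao1(list(S_obs = 10, F1 = 3, F2 = 0))$estimate, 13)
  expect_equal(chao1(list(S_obs = 10, F1 = 0, F2 = 0))$estimate, 10)
  ## from an abundance vector
  ab <- c(5, 3, 2, 2, 1, 1, 1, 1)       # S=8, F1=4, F2=2
  ch <- chao1(ab)
  expect_equal(ch$S_obs, 8)
  expect_equal(ch$F1, 4)
  expect_equal(ch$F2, 2)
  expect_equal(ch$estimate, 8 + 16 / 4)
  expect_equal(ch$variant, "classical")
  expect_equal(ch$cv, stats::sd(ab) / mean(ab))
  ## estimate never below the observed richness
  set.seed(74)
  for (i in 1:20) {
    x <- rpois(30, 2)
    expect_gte(chao1(x[x > 0])$estimate, sum(x > 0))
  }
})

test_that("accumulation curves behave at the boundaries and recover richness", {
  motus <- rep(1:10, times = c(8, 7, 6, 5, 4, 3, 2, 2, 1, 1))
  curve <- accumulation_curve(motus, sizes = c(5, length(motus)),
                              reps = 50, seed = 75)
  ## at the full sample size the observed richness is exact
  expect_equal(curve$S_mean[curve$n == length(motus)], 10)
  expect_lt(curve$S_mean[curve$n == 5], 10)
  ## a single species stays a single species at every size
  one <- accumulation_curve(rep(1, 20), sizes = c(1, 10, 20), reps = 10,
                            seed = 76)
  expect_true(all(one$S_mean == 1))
  expect_true(all(one$chao1_mean == 1))
  ## reproducible per seed
  c2 <- accumulation_curve(motus, sizes = c(5, length(motus)),
                           reps = 50, seed = 75)
  expect_identical(curve, c2)
  ## Chao1 at the full sample lands near the true richness of a
  ## simulated community with known species count
  set.seed(77)
  truth_comm <- sample(rep(1:25, times = pmax(1, rpois(25, 3))))
  ch <- chao1(as.integer(table(truth_comm)))
  expect_gte(ch$estimate, 25 - 5)
  expect_lte(ch$estimate, 25 + 15)
})
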