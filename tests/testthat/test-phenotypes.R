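test_that("zscores use the sample-SD convention and are idempotent", {
  expect_equal(zscores(c(0, 2)), c(-1, 1) / sqrt(2))
  expect_error(zscores(rep(3, 10)), "zero SD")
  expect_error(zscores(1), "at least 2")
  set.seed(1)
  x <- rnorm(100)
  expect_equal(zscores(zscores(x)), zscores(x), tolerance = 1e-12)
})

test_that("quantile bins follow the rank formulas", {
  set.seed(2)
  b <- quantile_bins(rnorm(3824), q = 0.05)
  expect_equal(sum(b == "high"), 192L)
  expect_equal(sum(b == "low"), 192L)

  b2 <- quantile_bins(rnorm(100), q = 0.05)
  expect_equal(as.vector(table(b2)[c("low", "high")]), c(5L, 5L))

  b3 <- quantile_bins(1:20, q = 0.05)
  expect_equal(which(b3 == "low"), 1L)
  expect_equal(which(b3 == "high"), 20L)

  # property: bin sizes are ceiling(q*n) and n - floor((1-q)*n) for all n, q
  set.seed(3)
  for (rep in 1:40) {
    q <- runif(1, 0.01, 0.49)
    n <- sample(ceiling(1 / q):500, 1)
    b <- quantile_bins(rnorm(n), q)
    expect_equal(sum(b == "low"), ceiling(q * n))
    expect_equal(sum(b == "high"), n - floor((1 - q) * n))
  }
  expect_error(quantile_bins(rnorm(100), q = 0.6), "q must be")
  expect_error(quantile_bins(rnorm(5), q = 0.05), "1/q")
})

test_that("ties in quantile bins break deterministically by strain id", {
  v <- rep(c(1, 2), each = 10)
  ids <- sprintf("s%02d", 20:1)
  b1 <- quantile_bins(v, 0.1, ids)
  b2 <- quantile_bins(v, 0.1, ids)
  expect_identical(b1, b2)
  expect_setequal(ids[b1 == "low"], c("s11", "s12"))  # lowest ids among ties
})

test_that("venn overlaps equal brute-force set arithmetic", {
  s <- factor(c("high", "low", "none", "none"), c("low", "none", "high"))
  e <- factor(c("none", "none", "high", "low"), c("low", "none", "high"))
  g <- c(FALSE, FALSE, FALSE, FALSE)
  v <- venn_overlaps(s, e, g)
  expect_true(all(v$pairwise[upper.tri(v$pairwise)] == 0))
  expect_equal(v$union, 4L)
  expect_equal(v$frac_single, 1)

  ids <- sprintf("s%02d", 1:20)
  s2 <- factor(rep("none", 20), c("low", "none", "high"))
  e2 <- s2
  s2[1:10] <- "high"; e2[1:10] <- "high"
  v2 <- venn_overlaps(s2, e2, rep(FALSE, 20), ids)
  expect_equal(v2$pairwise["S_high", "E_high"], 10L)
  expect_equal(v2$union, 10L)
  expect_equal(v2$frac_single, 0)

  set.seed(4)
  n <- 1000
  ids <- sprintf("g%04d", seq_len(n))
  s3 <- factor(sample(c("low", "none", "high"), n, TRUE, c(.05, .9, .05)),
               c("low", "none", "high"))
  e3 <- factor(sample(c("low", "none", "high"), n, TRUE, c(.05, .9, .05)),
               c("low", "none", "high"))
  g3 <- runif(n) < 0.1
  v3 <- venn_overlaps(s3, e3, g3, ids)
  # independent recomputation with logical indexing
  expect_equal(v3$pairwise["S_high", "E_low"],
               sum(s3 == "high" & e3 == "low"))
  expect_equal(v3$pairwise["S_low", "G_extreme"],
               sum(s3 == "low" & g3))
  expect_equal(v3$union,
               sum(s3 != "none" | e3 != "none" | g3))
})

test_that("pattern classification matches the threshold rules", {
  calls <- classify_patterns(c(2.5, 2.5), c(0.1, 1.0), c(0.3, 0.0))
  expect_equal(calls$class[1], "S+1/E0/G0")
  expect_true(calls$classified[1])
  expect_false(calls$classified[2])  # E intermediate
  expect_true(is.na(calls$class[2]))

  expect_error(classify_patterns(0, 0, 0, z_extreme = 0.4), "configuration")
})

test_that("grid enumeration reaches exactly 16 classes and never (0,0)", {
  zgrid <- c(-3, -2.5, -1.2, -0.4, 0, 0.4, 1.2, 2.5, 3)
  g <- expand.grid(Z_S = zgrid, Z_E = zgrid, Z_G = c(0, 3))
  calls <- classify_patterns(g$Z_S, g$Z_E, g$Z_G)
  reached <- unique(calls$class[calls$classified])
  expect_length(reached, 16L)
  expect_setequal(reached, pattern_classes())
  expect_false(any(calls$classified & calls$s_code == 0 & calls$e_code == 0))
  pm <- pattern_matrix(calls)
  expect_equal(sum(pm$n), sum(calls$classified))
})

test_that("raising the extremeness threshold never classifies new strains", {
  set.seed(5)
  n <- 500
  zs <- rnorm(n, sd = 1.5); ze <- rnorm(n, sd = 1.5); zg <- rnorm(n, sd = 1.5)
  lo <- classify_patterns(zs, ze, zg, z_extreme = 2)
  hi <- classify_patterns(zs, ze, zg, z_extreme = 2.8)
  expect_true(all(!hi$classified | lo$classified))
})

test_that("bootstrap co-occurrence matches exact enumeration on small universes", {
  universe <- letters[1:10]
  A <- c("a", "b"); B <- c("a", "b")
  res <- bootstrap_cooccurrence(A, B, universe, B = 10000, seed = 11)
  expect_equal(res$observed, 2L)
  # exhaustive enumeration over all ordered draws of both sets
  pairsA <- utils::combn(10, 2)
  pairsB <- utils::combn(10, 2)
  tot <- 0L; ge <- 0L
  for (i in seq_len(ncol(pairsA))) for (j in seq_len(ncol(pairsB))) {
    tot <- tot + 1L
    if (length(intersect(pairsA[, i], pairsB[, j])) >= 2L) ge <- ge + 1L
  }
  p_exact <- ge / tot
  se <- sqrt(p_exact * (1 - p_exact) / res$B)
  expect_lt(abs(res$p - p_exact), 3 * se + 2 / (res$B + 1))

  res2 <- bootstrap_cooccurrence(A, B, universe, B = 10000, seed = 11)
  expect_identical(res2$p, res$p)

  full <- bootstrap_cooccurrence(universe, B, universe, B = 1000, seed = 1)
  expect_equal(full$p, 1)

  expect_error(bootstrap_cooccurrence(c("zz"), B, universe), "outside")
  expect_error(bootstrap_cooccurrence(A, B, universe, B = 10), "B must be")
})

test_that("class membership test agrees with the hypergeometric tail", {
  universe <- sprintf("g%04d", 1:3824)
  phenotype <- universe[1:60]
  members <- c(universe[1:5], universe[100:106])  # 12 genes, overlap 5
  res <- class_membership_test(members, phenotype, universe, B = 10000,
                               seed = 21)
  expect_equal(res$observed, 5L)
  p_exact <- phyper(4, 60, 3824 - 60, 12, lower.tail = FALSE)
  se <- sqrt(p_exact * (1 - p_exact) / res$B)
  expect_lt(abs(res$p - p_exact), 3 * se + 2 / (res$B + 1))

  # disjoint sets with a small phenotype set: p near 1
  res0 <- class_membership_test(universe[200:211], phenotype, universe,
                                B = 1000, seed = 3)
  expect_gt(res0$p, 0.8)
})

test_that("the empirical p decreases monotonically in the observed overlap", {
  universe <- sprintf("g%03d", 1:200)
  res <- class_membership_test(universe[1:40], universe[1:80], universe,
                               B = 2000, seed = 7)
  p_at <- vapply(0:30, function(k) (1 + sum(res$null >= k)) / (res$B + 1),
                 numeric(1))
  expect_true(all(diff(p_at) <= 0))
  dense <- which(tabulate(res$null + 1L, 31L) > 0)
  expect_true(all(diff(p_at[dense]) < 0))
})

test_that("call_phenotypes combines quantile and Z schemes coherently", {
  cfg <- small_config(n_strains = 300, n_events = 200, seed = 40,
                      effect_classes = scaled_effect_classes(300))
  scr <- generate_screen(cfg)
  ss <- summarize_screen(scr$events, min_events = 100)
  ph <- call_phenotypes(decompose_screen(ss, scale = "log"))
  n <- nrow(ph)
  expect_equal(sum(ph$S_bin == "high"), ceiling(0.05 * n))
  # two-sided G extremes: union of both tails
  expect_equal(sum(ph$G_bin == "extreme"), 2L * ceiling(0.05 * n))
  expect_true(all(ph$classified == !is.na(ph$class)))
  expect_true(all(abs(ph$Z_S[ph$s_code == 1] ) > 2, na.rm = TRUE))
})
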