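test_that("scalar-product similarity has its geometric identities", {
  w <- c(0.2, 0.5, 0.8, 0.1)
  expect_equal(similarity(w, w), 1)
  expect_equal(similarity(c(1, 0, 0), c(0, 1, 1)), 0) # disjoint support
  expect_equal(similarity(c(1, 0, 1) / sqrt(2), c(1, 1, 0) / sqrt(2)), 0.5)
  expect_error(similarity(c(0, 0), c(1, 1)), "zero vector")
  # invariance to positive rescaling, over random draws
  set.seed(7)
  for (i in 1:20) {
    a <- runif(6); b <- runif(6)
    expect_equal(similarity(a, b), similarity(3.7 * a, 0.2 * b),
                 tolerance = 1e-12)
  }
})

test_that("matching recovers permutations and maximizes total similarity", {
  gt <- make_ground_truth(13, 5, seed = 3)
  Wa <- synergy_set(gt$W_true)
  perm <- c(4, 1, 5, 2, 3)
  Wb <- synergy_set(gt$W_true[, perm])
  m <- match_synergies(Wa, Wb)
  expect_equal(m$pairs$similarity, rep(1, 5), tolerance = 1e-12)
  expect_equal(order(perm), m$pairs$b) # the permutation is recovered

  # hand-built 2x2 similarity [[0.9, 0.2], [0.3, 0.8]] -> diagonal pairing
  a1 <- c(1, 0, 0); a2 <- c(0, 1, 0)
  b1 <- c(0.9, 0.3, sqrt(1 - 0.9^2 - 0.3^2))
  b2 <- c(0.2, 0.8, sqrt(1 - 0.2^2 - 0.8^2))
  m2 <- match_synergies(cbind(a1, a2), cbind(b1, b2))
  expect_equal(m2$pairs$b, c(1, 2))
  expect_equal(m2$total_similarity, 1.7, tolerance = 1e-12)

  # unequal orders: min(K_a, K_b) pairs, one column unmatched
  m3 <- match_synergies(Wa, synergy_set(cbind(gt$W_true, c(rep(0, 12), 1))))
  expect_identical(nrow(m3$pairs), 5L)
  expect_identical(m3$k_b, 6L)

  # global assignment beats every permutation (enumerated oracle)
  set.seed(15)
  Wx <- matrix(runif(6 * 4), 6, 4); Wy <- matrix(runif(6 * 4), 6, 4)
  mg <- match_synergies(Wx, Wy)
  S <- crossprod(sweep(Wx, 2, sqrt(colSums(Wx^2)), "/"),
                 sweep(Wy, 2, sqrt(colSums(Wy^2)), "/"))
  all_perms <- pracma::perms(1:4)
  totals <- apply(all_perms, 1, function(p) sum(S[cbind(1:4, p)]))
  expect_equal(mg$total_similarity, max(totals), tolerance = 1e-12)

  # greedy agrees with global on well-separated sets
  mgreedy <- match_synergies(Wa, Wb, method = "greedy")
  expect_equal(mgreedy$pairs, match_synergies(Wa, Wb)$pairs)

  expect_error(match_synergies(matrix(1, 3, 2), matrix(1, 4, 2)),
               "muscle counts")
})

test_that("the permutation null forms all pairs and behaves monotonically", {
  gt1 <- make_ground_truth(13, 5, seed = 1)
  gt2 <- make_ground_truth(13, 5, seed = 2)
  pool <- cbind(gt1$W_true, gt2$W_true)
  thr <- permutation_threshold(pool, n_random = 200, seed = 5)
  expect_identical(thr$n_pairs, as.integer(200 * 199 / 2))
  expect_gt(thr$threshold, 0); expect_lt(thr$threshold, 1)
  # bit-reproducible under the seed
  expect_identical(thr$threshold,
                   permutation_threshold(pool, n_random = 200, seed = 5)$threshold)
  # non-decreasing in the percentile
  t90 <- permutation_threshold(pool, n_random = 200, percentile = 90, seed = 5)
  t99 <- permutation_threshold(pool, n_random = 200, percentile = 99, seed = 5)
  expect_lte(t90$threshold, t99$threshold)
  # Bonferroni m = 4 moves the percentile to 98.75 and cannot lower it
  tb <- permutation_threshold(pool, n_random = 200, n_comparisons = 4, seed = 5)
  expect_equal(tb$percentile_used, 98.75)
  expect_gte(tb$threshold, thr$threshold)
  expect_error(permutation_threshold(matrix(numeric(0), 13, 0)), "pool")

  mm <- apply_threshold(match_synergies(gt1$W_true, gt1$W_true), thr)
  expect_true(all(mm$significant)) # self-match similarity 1 beats any null
  expect_equal(mm$threshold, thr$threshold)
})

test_that("fixed-basis NNLS activations are optimal nonnegative fits", {
  gt <- make_ground_truth(13, 4, seed = 6)
  W <- synergy_set(gt$W_true)
  set.seed(8)
  C0 <- matrix(runif(4 * 50), 4, 50)
  E <- gt$W_true %*% C0
  Cp <- nnls_activations(W, E)
  expect_gte(vaf(E, W, Cp)$gvaf, 99.99)
  # data outside the basis support fits to ~zero
  Wd <- matrix(0, 13, 2); Wd[1:2, 1] <- c(1, 1) / sqrt(2); Wd[3, 2] <- 1
  Eo <- matrix(0, 13, 5); Eo[10:13, ] <- 1
  expect_lt(max(nnls_activations(synergy_set(Wd, muscle_set(default_muscles())), Eo)$C), 1e-8)
  # matches a frozen-W multiplicative-update solver within tolerance
  set.seed(9)
  Er <- matrix(runif(13 * 50), 13, 50)
  Cmu <- matrix(runif(4 * 50, 0.1, 1), 4, 50)
  for (i in 1:4000) {
    Cmu <- Cmu * (crossprod(W$W, Er) / (crossprod(W$W, W$W %*% Cmu) + 1e-12))
  }
  Cn <- nnls_activations(W, Er)
  sse <- function(C) sum((Er - W$W %*% C)^2)
  expect_lte(sse(Cn$C), sse(Cmu) + 1e-6)
  expect_error(nnls_activations(W, matrix(1, 5, 3)), "muscles")
})

test_that("self-reconstruction loses essentially no variance", {
  fx <- small_reaching_dataset(seed = 21, n_reps = 2, n_synergies = 3)
  pooled <- preprocess_dataset(fx$ds)
  fit <- nnmf(pooled, 3, restarts = 5, max_iter = 500, tol = 1e-5, seed = 1)
  cv <- cross_validate(fit$W, pooled, fit$vaf$gvaf)
  expect_lt(abs(cv$gvaf_reconstructed - cv$gvaf_original), 0.1)
})

test_that("TOST equivalence follows the paired one-sided t construction", {
  x <- c(91, 92, 90.5, 93, 91.5, 92.2, 90.9, 91.8, 92.4, 91.1)
  # identical vectors: trivially equivalent
  r0 <- tost_equivalence(x, x)
  expect_true(r0$equivalent)
  # mean difference 10 with tiny spread: clearly not equivalent
  set.seed(3)
  y10 <- x - 10 + rnorm(10, sd = 1)
  expect_false(tost_equivalence(x, y10)$equivalent)
  # mean difference 2, SD ~2: equivalent at margin 5
  d <- c(rep(0, 5), rep(4, 5))
  r2 <- tost_equivalence(x, x - d)
  expect_true(r2$equivalent)
  # cross-check the upper one-sided p against stats::t.test
  ref <- stats::t.test(d, mu = 5, alternative = "less")$p.value
  expect_equal(r2$p_upper, ref, tolerance = 1e-12)
  ref_lo <- stats::t.test(d, mu = -5, alternative = "greater")$p.value
  expect_equal(r2$p_lower, ref_lo, tolerance = 1e-12)
  # degenerate zero-variance differences fall back to the exact decision
  rz <- tost_equivalence(c(90, 90), c(88, 88))
  expect_true(rz$equivalent)
  rz2 <- tost_equivalence(c(90, 90), c(80, 80))
  expect_false(rz2$equivalent)
  expect_error(tost_equivalence(1:3, 1:4), "paired")
})
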