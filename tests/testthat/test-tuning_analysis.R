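test_that("local-coordinate rotation matches the workspace geometry", {
  expect_equal(rotate_to_local(90, "Left"), 62)     # 28 deg clockwise
  expect_equal(rotate_to_local(90, "Distal"), 90)   # identity
  expect_equal(rotate_to_local(90, "Proximal"), 90)
  expect_equal(rotate_to_local(350, "Right"), 12.4) # wraps past 360
  expect_error(rotate_to_local(0, "Nowhere"), "rotation")
})

test_that("tuning curves aggregate activations per local direction", {
  dirs <- rep(rep(target_directions(), each = 2), each = 10) # 2 trials/dir
  trial_ids <- rep(seq_len(24), each = 10)
  # constant activation -> flat curve
  Cc <- activation_set(matrix(2.5, 2, length(dirs)), trial_index = trial_ids,
                       direction_deg = dirs)
  cur <- compute_tuning_curve(Cc, "Distal")
  expect_equal(unname(cur$values), matrix(2.5, 2, 12))
  expect_equal(cur$n_trials, rep(2L, 12))
  # linearity: doubling C doubles the curve
  set.seed(4)
  Cr <- matrix(runif(2 * length(dirs)), 2)
  c1 <- compute_tuning_curve(activation_set(Cr, trial_ids, dirs), "Distal")
  c2 <- compute_tuning_curve(activation_set(2 * Cr, trial_ids, dirs), "Distal")
  expect_equal(c2$values, 2 * c1$values, tolerance = 1e-12)
  # Left rotation relabels the direction axis
  cl <- compute_tuning_curve(activation_set(Cr, trial_ids, dirs), "Left")
  expect_equal(cl$directions_deg, sort(wrap_deg(target_directions() - 28)))
  # a direction with no trials is a named error
  keep <- dirs != 90
  expect_error(compute_tuning_curve(
    activation_set(Cr[, keep, drop = FALSE], trial_ids[keep], dirs[keep]),
    "Distal"), "90")
})

test_that("noiseless curves follow the rectified-cosine generative law", {
  gt <- make_ground_truth(13, 3, seed = 2, snr = Inf)
  # 5 repetitions so that rep-to-rep gain jitter averages out of the curve
  ds <- synthesize_dataset(gt, "reaching", "Distal", n_reps = 5, seed = 1,
                           fs_emg = 500, fs_aux = 500)
  # pool the generative activations over each trial's movement window
  cols <- lapply(ds$trials, function(tr) {
    tr$truth$C_true[, tr$truth$onset_sample:
                      min(tr$truth$offset_sample - 1, ncol(tr$emg)),
                    drop = FALSE]
  })
  dirs <- rep(vapply(ds$trials, function(tr) tr$meta$direction_deg,
                     numeric(1)),
              vapply(cols, ncol, integer(1)))
  Ctrue <- activation_set(do.call(cbind, cols), direction_deg = dirs)
  curve <- compute_tuning_curve(Ctrue, "Distal")
  for (k in 1:3) {
    law <- tuning_value(gt$preferred_dir_deg[k], gt$amplitude[k],
                        gt$tuning_offset[k], curve$directions_deg)
    expect_gt(stats::cor(curve$values[k, ], law), 0.99)
  }
})

test_that("tuning direction is the angle of the component vector sum", {
  dirs <- target_directions()
  v <- numeric(12); v[dirs == 90] <- 1
  td <- tuning_direction(v, dirs)
  expect_equal(td$angle_deg, 90)
  # equal mass at 0 and 90 -> 45
  v2 <- numeric(12); v2[dirs %in% c(0, 90)] <- 1
  expect_equal(tuning_direction(v2, dirs)$angle_deg, 45, tolerance = 1e-9)
  # perfect cancellation -> untuned flag, no exception
  v3 <- numeric(12); v3[dirs %in% c(0, 180)] <- 1
  td3 <- tuning_direction(v3, dirs)
  expect_true(td3$untuned)
  expect_lt(td3$resultant_length, 1e-9)
  td0 <- tuning_direction(numeric(12), dirs)
  expect_true(td0$untuned)
})

test_that("the change-point threshold matches an exhaustive oracle", {
  # 500 zeros then 500 ones: split at the boundary, t = 1
  x <- c(rep(0, 500), rep(1, 500))
  at <- activation_threshold(x)
  expect_equal(at$change_index, 500L)
  expect_equal(at$t, 1)
  bf <- brute_force_changepoint(x)
  expect_equal(at$change_index, bf$change_index)
  # linear ramp: split at the midpoint (within one index of n/2)
  ramp <- seq(0, 1, length.out = 200)
  ar <- activation_threshold(ramp)
  expect_lte(abs(ar$change_index - 100), 1)
  expect_equal(ar$change_index, brute_force_changepoint(ramp)$change_index)
  # two separated Gaussian clusters: split within 1% of the true boundary
  set.seed(6)
  g <- c(rnorm(400, 1, 0.05), rnorm(600, 5, 0.05))
  ag <- activation_threshold(g)
  expect_lte(abs(ag$change_index - 400), 10)
  expect_equal(ag$change_index, brute_force_changepoint(g)$change_index)
  # random sequences agree with the oracle exactly
  for (s in 1:20) {
    set.seed(s)
    y <- rexp(150, rate = runif(1, 0.5, 2))
    expect_identical(activation_threshold(y)$change_index,
                     brute_force_changepoint(y)$change_index)
  }
  expect_error(activation_threshold(rep(2, 50)), "no change point")
})

test_that("active-synergy counts are strict exceedances and monotone in t", {
  dirs <- target_directions()
  vals <- rbind(tuning_value(0, 1, 0, dirs), tuning_value(180, 1, 0, dirs))
  curve <- structure(list(values = vals, directions_deg = dirs,
                          n_trials = rep(1L, 12), location = "Distal"),
                     class = "tuning_curve")
  expect_equal(unname(count_active_synergies(curve, 10)), rep(0L, 12))
  pos <- structure(list(values = vals + 0.1, directions_deg = dirs,
                        n_trials = rep(1L, 12), location = "Distal"),
                   class = "tuning_curve")
  expect_equal(unname(count_active_synergies(pos, 0)), rep(2L, 12))
  # monotone: raising t never increases any count
  ts <- seq(0, 1.2, by = 0.1)
  counts <- vapply(ts, function(t0) count_active_synergies(curve, t0),
                   integer(12))
  expect_true(all(apply(counts, 1, function(r) all(diff(r) <= 0))))
})

test_that("circular ANOVA separates concentrated groups and not clones", {
  a <- c(350, 355, 0, 5, 10, 358, 2, 7)
  same <- circular_anova(list(a, a, a))
  expect_lt(same$F, 1e-6)
  expect_gt(same$p, 0.99)
  g0 <- rvonmises(10, 0, 50, seed = 1)
  g90 <- rvonmises(10, 90, 50, seed = 2)
  expect_lt(circular_anova(list(g0, g90))$p, 0.001)
  # degenerate group: four angles cancelling to zero resultant
  expect_error(circular_anova(list(c(0, 90, 180, 270), a)), "zero resultant")
  expect_error(circular_anova(list(a)), "2 groups")
  # low concentration triggers the assumption warning
  set.seed(2)
  expect_warning(circular_anova(list(runif(20, 0, 360), runif(20, 0, 360))),
                 "concentration")
})

test_that("the two-sample circular test respects the corrected level", {
  a <- rvonmises(12, 10, 30, seed = 3)
  r_same <- circular_two_sample(a, a)
  expect_gt(r_same$p, 0.99)
  expect_false(r_same$significant)
  b <- rvonmises(12, 190, 30, seed = 4)
  r_diff <- circular_two_sample(a, b)
  expect_lt(r_diff$p, 0.001)
  expect_true(r_diff$significant)
  expect_equal(r_diff$alpha_corrected, 0.0125)
  # minimal n: duplicated angles still return a defined result
  r_min <- circular_two_sample(c(10, 12), c(11, 13))
  expect_true(is.finite(r_min$p))
})

test_that("opposing preferred directions yield opposing tuning directions", {
  gt <- make_ground_truth(13, 2, seed = 5, preferred_dir_deg = c(40, 220),
                          snr = 10)
  ds <- synthesize_dataset(gt, "reaching", "Distal", n_reps = 2, seed = 3,
                           fs_emg = 500, fs_aux = 500)
  pooled <- preprocess_dataset(ds)
  fit <- nnmf(pooled, 2, restarts = 5, max_iter = 500, tol = 1e-5, seed = 1)
  m <- recovered_vs_truth(fit, pooled, gt)
  curve <- compute_tuning_curve(fit$C, "Distal")
  td <- tuning_direction(curve)
  gap <- abs(td$angle_deg[1] - td$angle_deg[2]) %% 360
  gap <- min(gap, 360 - gap)
  expect_lt(abs(gap - 180), 5)
})
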