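test_that("wavelet ECG suppression removes spikes and spares clean signal", {
  gt <- make_ground_truth(13, 3, seed = 6)
  tr <- synthesize_trial(gt, trial_meta("isometric", "Distal", 30), seed = 2)
  con <- add_ecg_artifact(tr, rate_hz = 1.2, amplitude = 0.6, seed = 4)
  ch <- "UT" # contaminated channel
  x_clean <- tr$emg[ch, ]
  x_con <- con$emg[ch, ]
  y <- remove_ecg(x_con, fs = 1000)

  # clean channel passes through nearly unchanged
  y_clean <- remove_ecg(x_clean, fs = 1000)
  expect_lt(sqrt(mean((y_clean - x_clean)^2)) / sqrt(mean(x_clean^2)), 0.05)

  # spike neighborhood = template half-width (30 ms) + largest clipped
  # wavelet scale (32 ms)
  spike_idx <- unlist(lapply(con$ecg_artifact$centers_s, function(ct) {
    round(ct * 1000) + (-64:64)
  }))
  spike_idx <- spike_idx[spike_idx >= 1 & spike_idx <= length(x_con)]
  off_idx <- setdiff(seq_along(x_con), spike_idx)
  rms <- function(v) sqrt(mean(v^2))
  # artifact energy halved inside spike windows ...
  expect_lt(rms(y[spike_idx] - x_clean[spike_idx]),
            0.5 * rms(x_con[spike_idx] - x_clean[spike_idx]))
  # ... while off-spike signal moves by < 10%
  expect_lt(rms(y[off_idx] - x_clean[off_idx]), 0.1 * rms(x_clean[off_idx]))
  # no energy added, zero maps to zero, short series rejected
  expect_lte(sum(y^2), sum(x_con^2) * (1 + 1e-9))
  expect_equal(remove_ecg(numeric(256)), numeric(256))
  expect_error(remove_ecg(numeric(32), levels = 6), "too short")
})

test_that("envelope chain applies its steps in order", {
  # constants die at the mean-subtraction step
  expect_equal(envelope(rep(3.7, 500), fs = 1000), rep(0, 500),
               tolerance = 1e-9)
  # |sin| of a 100 Hz unit sinusoid low-passes to its mean 2/pi
  t <- seq(0, 2, by = 1e-3)
  x <- sin(2 * pi * 100 * t)
  y <- envelope(x, fs = 1000)
  mid <- y[500:1500] # away from filter edges
  expect_lt(abs(mean(mid) - 2 / pi) / (2 / pi), 0.05)
  # cutoff at/above Nyquist is rejected
  expect_error(envelope(x, fs = 1000, cutoff_hz = 500), "Nyquist")
})

test_that("envelope of a noiseless trial tracks the true activation profile", {
  gt <- make_ground_truth(13, 3, seed = 9, snr = Inf)
  tr <- synthesize_trial(gt, trial_meta("isometric", "Distal", 60), seed = 1)
  m <- which.max(rowSums(tr$emg)) # most active muscle
  env <- envelope(tr$emg[m, ], fs = 1000, baseline_window = tr$baseline_window)
  expect_gt(stats::cor(env, tr$truth$clean[m, ]), 0.95)
})

test_that("force onset detection follows the 3 x SD rule strictly", {
  # deterministic baseline with known spread, then a step
  base <- rep(c(2, 0, -2, 0), 25) # 100 samples, mean 0
  dev <- abs(base - mean(base))   # |Fx - mean| during baseline
  thr <- mean(dev) + 3 * stats::sd(dev)
  mk <- function(step) cbind(c(base, rep(step, 20)), 0, 0)
  expect_error(
    detect_force_onset_offset(mk(0), fs_aux = 20, baseline_window = c(1, 101),
                              guard_s = 0),
    "no onset")
  # a step exactly at threshold is NOT an onset; epsilon above is
  expect_error(
    detect_force_onset_offset(mk(thr), fs_aux = 20, baseline_window = c(1, 101),
                              guard_s = 0),
    "no onset")
  ev <- detect_force_onset_offset(mk(thr + 1e-9), fs_aux = 20,
                                  baseline_window = c(1, 101), guard_s = 0)
  expect_equal(ev$onset_aux, 101)
  expect_equal(ev$rule, "force_3sd")
  # aux index 101 at 20 Hz -> EMG sample at 1 kHz
  expect_equal(ev$onset_sample, as.integer(round(100 / 20 * 1000) + 1))
})

test_that("force onset on synthesized trials lands within one aux sample", {
  gt <- make_ground_truth(13, 3, seed = 11)
  for (s in 1:5) {
    tr <- synthesize_trial(gt, trial_meta("isometric", "Distal", 90), seed = s)
    bw_aux <- c(1, round((tr$baseline_window[2] - 1) / 1000 * 20) + 1)
    ev <- detect_force_onset_offset(tr$aux, fs_aux = 20, baseline_window = bw_aux,
                                    fs_emg = 1000)
    expect_lte(abs(ev$onset_sample - tr$truth$onset_sample), 1000 / 20)
  }
})

test_that("movement onset/offset follow the 10% peak-speed rule", {
  tau <- seq(0, 1, length.out = 301)
  v <- 30 * tau^2 * (1 - tau)^2
  ev <- detect_movement_onset_offset(v, fs_aux = 1000, fs_emg = 1000)
  # symmetric profile: onset and offset equidistant from the peak
  pk <- which.max(v)
  expect_lte(abs((pk - ev$onset_aux) - (ev$offset_aux - pk)), 1)
  # impulse: onset = offset - 1 = the nonzero sample
  imp <- c(rep(0, 10), 1, rep(0, 10))
  evi <- detect_movement_onset_offset(imp)
  expect_equal(evi$onset_aux, 11)
  expect_equal(evi$offset_aux, 12)
  # fraction 0: onset at the first strictly positive sample
  ev0 <- detect_movement_onset_offset(c(0, 0, 0.01, 0.5, 1, 0.2), fraction = 0)
  expect_equal(ev0$onset_aux, 3)
  expect_error(detect_movement_onset_offset(rep(0, 10)), "no movement")
  expect_error(detect_movement_onset_offset(c(-1, 1)), "nonnegative")
})

test_that("trim-and-resample yields exactly 150 samples and is exact on its grid", {
  ev <- structure(list(onset_sample = 11L, offset_sample = 161L),
                  class = "event_marks")
  m <- matrix(runif(2 * 200), 2, 200)
  out <- trim_and_resample(m, ev, length = 150)
  expect_identical(ncol(out), 150L)
  expect_equal(out, m[, 11:160], tolerance = 1e-12, # window already 150 wide
               ignore_attr = TRUE)
  # a linear ramp stays linear with preserved endpoints
  ramp <- matrix(seq(0, 1, length.out = 200), 1, 200)
  ev2 <- structure(list(onset_sample = 21L, offset_sample = 101L),
                   class = "event_marks")
  out2 <- trim_and_resample(ramp, ev2, length = 150)
  expect_equal(out2[1, 1], ramp[1, 21], tolerance = 1e-12)
  expect_equal(out2[1, 150], ramp[1, 100], tolerance = 1e-12)
  expect_equal(max(abs(diff(diff(out2[1, ])))), 0, tolerance = 1e-12)
  expect_error(trim_and_resample(m, structure(list(onset_sample = 5L,
    offset_sample = 6L), class = "event_marks")), "shorter than 2")
})

test_that("pooling concatenates, variance-normalizes and is scale-aware", {
  set.seed(31)
  mats <- replicate(60, matrix(runif(13 * 150, 0.1, 1), 13, 150),
                    simplify = FALSE)
  dirs <- rep(target_directions(), each = 5)
  pooled <- build_pooled_emg(mats, dirs, muscle_set(), normalize = "variance")
  expect_identical(dim(pooled$matrix), c(13L, 9000L))
  expect_true(all(pooled$matrix >= 0) && all(is.finite(pooled$matrix)))
  # stored divisors reproduce the original scale
  orig <- pooled$matrix * pooled$muscle_variances
  expect_equal(orig, do.call(cbind, mats), tolerance = 1e-9,
               ignore_attr = TRUE)
  # scaling one muscle by 10 scales its variance by 100, its row by 1/10
  mats10 <- lapply(mats, function(m) { m[4, ] <- 10 * m[4, ]; m })
  pooled10 <- build_pooled_emg(mats10, dirs, muscle_set())
  expect_equal(pooled10$matrix[4, ], 0.1 * pooled$matrix[4, ],
               tolerance = 1e-9)
  # re-normalizing an already normalized matrix is not a no-op
  renorm <- build_pooled_emg(list(pooled$matrix), 0, muscle_set())
  expect_false(isTRUE(all.equal(renorm$muscle_variances,
                                rep(1, 13), check.attributes = FALSE)))
  # zero-variance muscle is a named error
  matsz <- lapply(mats, function(m) { m[2, ] <- 1; m })
  expect_error(build_pooled_emg(matsz, dirs, muscle_set()), "BI")
})

test_that("the dataset-level pipeline enforces stage order end to end", {
  fx <- small_reaching_dataset(seed = 12, n_reps = 2)
  pooled <- preprocess_dataset(fx$ds)
  expect_s3_class(pooled, "pooled_emg")
  expect_identical(dim(pooled$matrix), c(13L, 24L * 150L))
  expect_length(pooled$events, 24)
  expect_true(all(pooled$matrix >= 0))
  expect_identical(length(pooled$direction_deg), ncol(pooled$matrix))
})
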