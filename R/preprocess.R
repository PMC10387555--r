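# ---- undecimated wavelet decomposition -----------------------------------

# A trous (undecimated) Haar-type decomposition with edge replication.
# a_j = (a_{j-1} + shift(a_{j-1}, 2^(j-1))) / 2 ; d_j = a_{j-1} - a_j.
# Reconstruction is exact by telescoping: x = a_L + sum_j d_j.
swt_atrous <- function(x, levels) {
  a <- x
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    s <- 2L^(j - 1L)
    idx <- pmax(seq_along(a) - s, 1L)
    a_next <- (a + a[idx]) / 2
    details[[j]] <- a - a_next
    a <- a_next
  }
  list(approx = a, details = details)
}

#' Suppress ECG artifacts in one EMG channel
#'
#' Decomposes the channel with an undecimated (a trous) Haar wavelet
#' transform to `levels` scales and clips the magnitude of each scale's
#' detail coefficients at a robust local threshold: `k_mad` times a running
#' MAD (~0.5 s window) of that scale's coefficients about their median.
#' Cardiac spikes are brief, large outliers against the local coefficient
#' scale at the QRS scales, so clipping removes them, while artifact-free
#' EMG stays within its own local scale and passes nearly unchanged; the
#' approximation (the envelope's own band) is never touched.
#' Reconstruction is the exact additive inverse of the decomposition.
#'
#' @param x Numeric series (one channel).
#' @param fs Sampling rate in Hz (kept for interface symmetry; the scales are
#'   sample-based).
#' @param levels Decomposition depth (default 6; series must have at least
#'   `2^levels` samples).
#' @param k_mad Robust threshold multiplier (default 4).
#' @return The cleaned series, same length as `x`.
#' @export
remove_ecg <- function(x, fs = 1000, levels = 6, k_mad = 4) {
  if (length(x) < 2^levels) {
    stop_emg("series of length %d is too short for a %d-level decomposition",
             length(x), levels, class = "emg_decomposition")
  }
  dec <- swt_atrous(x, levels)
  # The robust scale is a running MAD (~0.5 s window): EMG coefficient
  # magnitude tracks activity, while a cardiac spike is far briefer than
  # the window and so always stands out from its local scale. The
  # approximation (the envelope's own band) is left untouched.
  # the local scale varies on the ~0.5 s timescale, so the running median
  # is computed on an 8x decimated grid and interpolated back
  n <- length(x)
  stride <- 8L
  sub <- seq(1L, n, by = stride)
  w <- min(63L, length(sub) - (1 - length(sub) %% 2))
  for (j in seq_along(dec$details)) {
    d <- dec$details[[j]]
    med <- stats::median(d)
    base <- stats::runmed(abs(d[sub] - med), k = w)
    local_mad <- 1.4826 * stats::approx(sub, base, xout = seq_len(n),
                                        rule = 2)$y
    thr <- k_mad * local_mad
    dec$details[[j]] <- pmin(pmax(d, med - thr), med + thr)
  }
  dec$approx + Reduce(`+`, dec$details)
}

#' Compute the EMG envelope of one channel
#'
#' Applies the envelope chain in its fixed order: (1) subtraction of the
#' whole-trial mean (DC offset removal), (2) full-wave rectification,
#' (3) subtraction of the mean rectified baseline, (4) zero-phase
#' (forward-backward) Butterworth low-pass filtering, (5) clipping of
#' negative residues to zero. Forward-backward filtering doubles the
#' effective order but removes group delay, which would otherwise bias
#' onset-aligned averaging.
#'
#' @param x Numeric series (one channel, raw or envelope-domain).
#' @param fs Sampling rate (Hz).
#' @param baseline_window Half-open interval `c(start, end)` of the rest
#'   period, or `NULL` to skip baseline subtraction.
#' @param cutoff_hz Low-pass cutoff (default 10 Hz); must be below fs/2.
#' @param order Butterworth order (default 4).
#' @return Nonnegative envelope series.
#' @export
envelope <- function(x, fs, baseline_window = NULL, cutoff_hz = 10, order = 4) {
  if (cutoff_hz >= fs / 2) {
    stop_emg("cutoff %g Hz is at or above the Nyquist frequency %g Hz",
             cutoff_hz, fs / 2, class = "emg_nyquist")
  }
  if (!is.null(baseline_window)) {
    bw <- as.integer(baseline_window)
    if (bw[1] < 1L || bw[2] > length(x) + 1L || bw[2] <= bw[1]) {
      stop_emg("baseline_window outside the series", class = "emg_invalid")
    }
  }
  y <- abs(x - mean(x))
  if (!is.null(baseline_window)) {
    y <- y - mean(y[bw[1]:(bw[2] - 1L)])
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  y <- signal::filtfilt(bf, y)
  pmax(y, 0)
}

#' Detect force onset and offset (isometric trials)
#'
#' Onset is the first auxiliary sample at which the planar force deviation
#' from the baseline mean force strictly exceeds its own baseline mean by
#' `sd_mult` (default 3) times the baseline standard deviation; offset is
#' the first subsequent sample strictly below that threshold, or the trial
#' end if the force never falls back. The deviation is the Euclidean norm of `(Fx, Fy)` minus the
#' baseline mean force: the task is horizontal, so Fz is ignored. The
#' baseline statistics exclude the last `guard_s` seconds of the declared
#' baseline window as a guard band against anticipatory activity. Indices
#' are reported on the EMG timebase (half-open).
#'
#' @param force n-by-3 (or n-by-2) force matrix at `fs_aux`.
#' @param fs_aux Force sampling rate (Hz).
#' @param baseline_window Half-open interval on the auxiliary timebase.
#' @param fs_emg EMG sampling rate used to convert indices.
#' @param sd_mult Threshold multiplier (default 3).
#' @param guard_s Guard band stripped from the end of the baseline (default
#'   0.5 s).
#' @return An `event_marks` list: `onset_sample`, `offset_sample` (EMG
#'   timebase), `onset_aux`, `offset_aux`, `rule`, `baseline_mean`,
#'   `baseline_sd`.
#' @export
detect_force_onset_offset <- function(force, fs_aux, baseline_window,
                                      fs_emg = 1000, sd_mult = 3,
                                      guard_s = 0.5) {
  force <- as.matrix(force)
  n <- nrow(force)
  bw <- as.integer(baseline_window)
  if (bw[1] < 1L || bw[2] > n + 1L || bw[2] <= bw[1]) {
    stop_emg("baseline_window outside the force series", class = "emg_invalid")
  }
  guard <- round(guard_s * fs_aux)
  b_end <- max(bw[1] + 1L, bw[2] - guard)
  bidx <- bw[1]:(b_end - 1L)
  mu <- colMeans(force[bidx, 1:2, drop = FALSE])
  dev <- sqrt((force[, 1] - mu[1])^2 + (force[, 2] - mu[2])^2)
  # the deviation magnitude has a positive baseline mean (Rayleigh-like
  # under noise), so the 3 x SD rule is applied about that mean
  base_mu <- mean(dev[bidx])
  base_sd <- stats::sd(dev[bidx])
  thr <- base_mu + sd_mult * base_sd
  search <- bw[2]:n
  over <- search[dev[search] > thr]
  if (length(over) == 0L) {
    stop_emg("force never exceeds %g x baseline SD: no onset found", sd_mult,
             class = "emg_no_onset")
  }
  onset_aux <- over[1]
  later <- if (onset_aux < n) (onset_aux + 1L):n else integer(0)
  under <- later[dev[later] < thr]
  offset_aux <- if (length(under)) under[1] else n + 1L
  aux_to_emg <- function(i) as.integer(round((i - 1) / fs_aux * fs_emg) + 1L)
  structure(
    list(onset_sample = aux_to_emg(onset_aux),
         offset_sample = aux_to_emg(offset_aux),
         onset_aux = onset_aux, offset_aux = offset_aux,
         rule = "force_3sd", baseline_mean = mu, baseline_sd = base_sd),
    class = "event_marks"
  )
}

#' Detect movement onset and offset from hand speed (reaching trials)
#'
#' Onset is the first sample with speed strictly above `fraction` (default
#' 10%) of the peak speed; offset is the first sample after the global peak
#' strictly below that threshold, or the trial end if speed never falls
#' back.
#'
#' @param speed Nonnegative speed series at `fs_aux`.
#' @param fraction Threshold fraction of the maximum (default 0.10).
#' @param fs_aux,fs_emg Sampling rates used to convert indices to the EMG
#'   timebase (defaults assume the speed is already on the EMG timebase).
#' @return An `event_marks` list (see [detect_force_onset_offset()]), with
#'   `rule = "speed_10pct"`.
#' @export
detect_movement_onset_offset <- function(speed, fraction = 0.10,
                                         fs_aux = 1000, fs_emg = 1000) {
  if (any(speed < 0)) stop_emg("speed must be nonnegative", class = "emg_invalid")
  if (max(speed) <= 0) {
    stop_emg("all-zero speed trace: no movement found", class = "emg_no_onset")
  }
  n <- length(speed)
  thr <- fraction * max(speed)
  onset_aux <- which(speed > thr)[1]
  pk <- which.max(speed)
  later <- if (pk < n) (pk + 1L):n else integer(0)
  under <- later[speed[later] < thr]
  offset_aux <- if (length(under)) under[1] else n + 1L
  aux_to_emg <- function(i) as.integer(round((i - 1) / fs_aux * fs_emg) + 1L)
  structure(
    list(onset_sample = aux_to_emg(onset_aux),
         offset_sample = aux_to_emg(offset_aux),
         onset_aux = onset_aux, offset_aux = offset_aux,
         rule = "speed_10pct", baseline_mean = NA_real_,
         baseline_sd = NA_real_),
    class = "event_marks"
  )
}

#' Trim a trial to its events and resample to a fixed length
#'
#' Linearly interpolates each muscle row of the trimmed window
#' (`onset_sample` to `offset_sample`, half-open) onto `length` equispaced
#' points, endpoints inclusive, so that every trial contributes equally to
#' synergy extraction. Linear interpolation of nonnegative data stays
#' nonnegative.
#'
#' @param env_matrix Muscles-by-samples envelope matrix.
#' @param events An `event_marks` list (EMG-timebase indices).
#' @param length Output samples per trial (default 150).
#' @return Muscles-by-`length` matrix.
#' @export
trim_and_resample <- function(env_matrix, events, length = 150) {
  on <- events$onset_sample
  off <- min(events$offset_sample, ncol(env_matrix) + 1L)
  if (off - on < 2L) {
    stop_emg("trimmed window [%d, %d) is shorter than 2 samples", on, off,
             class = "emg_trim")
  }
  win <- on:(off - 1L)
  grid <- seq(win[1], win[base::length(win)], length.out = length)
  out <- t(apply(env_matrix[, , drop = FALSE], 1, function(row) {
    stats::approx(win, row[win], xout = grid)$y
  }))
  if (!is.null(rownames(env_matrix))) rownames(out) <- rownames(env_matrix)
  out
}

#' Pool trimmed trials into one normalized EMG matrix
#'
#' Concatenates the trials horizontally in order and divides each muscle row
#' by that muscle's variance computed over the whole concatenated row (the
#' standard-deviation divisor is available via `normalize = "sd"`), so that
#' high-variance muscles do not dominate the factorization. The divisors are
#' stored so the original scale can be recovered. Note the operation is not
#' idempotent: renormalizing an already-normalized matrix changes it again.
#'
#' @param mats List of muscles-by-length matrices (one per trial).
#' @param direction_deg Numeric vector, one target direction per trial.
#' @param muscles A [muscle_set()].
#' @param normalize `"variance"` (default) or `"sd"`.
#' @return A `pooled_emg` list: `matrix` (muscles x n_trials*length),
#'   `trial_index` and `direction_deg` per column, `muscle_variances`,
#'   `resample_length`.
#' @export
build_pooled_emg <- function(mats, direction_deg, muscles,
                             normalize = "variance") {
  stopifnot(length(mats) == length(direction_deg), length(mats) >= 1L)
  len <- ncol(mats[[1]])
  if (!all(vapply(mats, ncol, integer(1)) == len)) {
    stop_emg("all trials must have the same resampled length", class = "emg_invalid")
  }
  mat <- do.call(cbind, mats)
  rownames(mat) <- unclass(muscles)
  v <- apply(mat, 1, stats::var)
  if (any(v <= 0)) {
    stop_emg("muscle(s) with zero variance: %s",
             paste(unclass(muscles)[v <= 0], collapse = ", "),
             class = "emg_degenerate_channel")
  }
  div <- if (normalize == "sd") sqrt(v) else v
  mat <- mat / div
  structure(
    list(matrix = mat,
         trial_index = rep(seq_along(mats), each = len),
         direction_deg = rep(as.numeric(direction_deg), each = len),
         muscle_variances = div, muscles = muscles,
         resample_length = len, normalize = normalize),
    class = "pooled_emg"
  )
}

#' Run the full preprocessing chain on a dataset
#'
#' The public entry point that enforces the stage order on every trial:
#' ECG artifact suppression (optional), envelope extraction, event detection
#' from the auxiliary trace (3 x SD force rule for isometric trials, 10%
#' peak-speed rule for reaching), trimming (isometric trials are trimmed
#' from force onset to the trial end; reaching trials from movement onset to
#' offset), 150-sample time normalization, concatenation and per-muscle
#' variance normalization.
#'
#' @param dataset An [emg_dataset()]; trials flagged `excluded` are dropped.
#' @param config A [pipeline_config()].
#' @return A `pooled_emg` with the per-trial `event_marks` attached as
#'   `$events`.
#' @export
preprocess_dataset <- function(dataset, config = pipeline_config()) {
  stopifnot(inherits(dataset, "emg_dataset"))
  trials <- Filter(function(tr) !tr$meta$excluded, dataset$trials)
  if (length(trials) == 0L) stop_emg("no non-excluded trials", class = "emg_invalid")
  mats <- vector("list", length(trials))
  evs <- vector("list", length(trials))
  dirs <- numeric(length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    env <- tr$emg
    for (m in seq_len(nrow(env))) {
      ch <- env[m, ]
      if (isTRUE(config$ecg$enabled)) {
        ch <- remove_ecg(ch, fs = tr$fs_emg, levels = config$ecg$levels,
                         k_mad = config$ecg$k_mad)
      }
      env[m, ] <- envelope(ch, fs = tr$fs_emg,
                           baseline_window = tr$baseline_window,
                           cutoff_hz = config$filter$cutoff_hz,
                           order = config$filter$order)
    }
    aux_bw <- emg_window_to_aux(tr$baseline_window, tr$fs_emg, tr$fs_aux)
    ev <- if (tr$meta$task == "isometric") {
      e <- detect_force_onset_offset(tr$aux, fs_aux = tr$fs_aux,
                                     baseline_window = aux_bw,
                                     fs_emg = tr$fs_emg,
                                     sd_mult = config$onset$force_sd_mult,
                                     guard_s = config$onset$guard_s)
      e$offset_sample <- ncol(tr$emg) + 1L # trim to trial end
      e
    } else {
      detect_movement_onset_offset(tr$aux,
                                   fraction = config$onset$speed_fraction,
                                   fs_aux = tr$fs_aux, fs_emg = tr$fs_emg)
    }
    evs[[i]] <- ev
    mats[[i]] <- trim_and_resample(env, ev, length = config$resample_length)
    dirs[i] <- tr$meta$direction_deg
  }
  pooled <- build_pooled_emg(mats, dirs, dataset$muscles,
                             normalize = config$normalize)
  pooled$events <- evs
  pooled
}

# convert a half-open EMG-timebase window to the auxiliary timebase
emg_window_to_aux <- function(win, fs_emg, fs_aux) {
  c(round((win[1] - 1) / fs_emg * fs_aux) + 1L,
    round((win[2] - 1) / fs_emg * fs_aux) + 1L)
}
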