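#' Default task timing for the synthetic generator
#'
#' Isometric trials: 5 s rest baseline, a 0.2 s reaction delay, a 0.5 s force
#' ramp and a 1 s hold at the target, giving a 6.7 s trial trimmed from force
#' onset to the trial end. Reaching trials: 1 s rest baseline, movement onset
#' at 1.2 s, a 0.3 s minimum-jerk reach with the EMG burst slightly leading
#' the speed peak, 2 s total.
#'
#' @return Nested list of per-task envelope/timing parameters (seconds).
#' @export
default_envelope_params <- function() {
  list(
    isometric = list(baseline_s = 5, delay_s = 0.2, ramp_s = 0.5, hold_s = 1),
    reaching = list(baseline_s = 1, move_onset_s = 1.2, move_dur_s = 0.3,
                    burst_lead_s = 0.05, burst_width_s = 0.07, trial_s = 2)
  )
}

#' Draw a ground-truth generative model
#'
#' Ground truth for synthetic EMG: a nonnegative muscles-by-K synergy matrix
#' with unit-norm columns and sparse dominant-muscle structure (each synergy
#' is dominated by 2-3 muscles: two of its own plus at most one muscle
#' shared with no other synergy's dominant set, over a weak background), a
#' preferred direction per synergy spread over the circle, a positive gain
#' and a small direction-independent activation baseline per synergy.
#'
#' @param n_muscles Number of muscles (default 13).
#' @param n_synergies Number of synergies K (must not exceed `n_muscles`).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param muscles Optional muscle labels (length `n_muscles`).
#' @param W_true Optional explicit nonnegative weight matrix
#'   (`n_muscles x n_synergies`); columns are renormalized. Overrides the
#'   random draw, e.g. to build sets with controlled support overlap.
#' @param preferred_dir_deg Optional explicit preferred directions (length K);
#'   by default K directions evenly spaced with a seeded rotation offset.
#' @param amplitude Optional per-synergy tuning gains (default drawn in
#'   `[0.8, 1.2]`).
#' @param tuning_offset Optional per-synergy direction-independent baseline
#'   (default 0.05).
#' @param snr Envelope signal-to-noise ratio (per-sample signal power over
#'   noise power on the active envelope; default 10).
#' @param envelope_params Task timing, see [default_envelope_params()].
#' @return A `ground_truth` list with fields `W_true`, `preferred_dir_deg`,
#'   `amplitude`, `tuning_offset`, `envelope_params`, `snr`, `seed`.
#' @export
make_ground_truth <- function(n_muscles = 13, n_synergies = 5, seed = 1,
                              muscles = NULL, W_true = NULL,
                              preferred_dir_deg = NULL, amplitude = NULL,
                              tuning_offset = NULL, snr = 10,
                              envelope_params = default_envelope_params()) {
  if (n_synergies > n_muscles) {
    stop_emg("cannot draw %d synergies from %d muscles (rank bound)",
             n_synergies, n_muscles, class = "emg_rank")
  }
  if (snr <= 0) stop_emg("snr must be > 0", class = "emg_invalid")
  muscles <- muscles %||%
    (if (n_muscles == 13) default_muscles() else sprintf("M%02d", seq_len(n_muscles)))
  with_seed(seed, {
    W <- matrix(0, n_muscles, n_synergies,
                dimnames = list(muscles, sprintf("syn%d", seq_len(n_synergies))))
    if (!is.null(W_true)) {
      stopifnot(nrow(W_true) == n_muscles, ncol(W_true) == n_synergies,
                all(W_true >= 0))
      W[] <- sweep(W_true, 2, sqrt(colSums(W_true^2)), "/")
    } else {
    # each synergy is dominated by 2 muscles of its own (distinct muscle
    # groups, as in real upper-limb synergies); muscles left over after the
    # exclusive assignment are shared at moderate weight so every recorded
    # muscle participates in at least one synergy; weak background elsewhere
    exclusive <- if (2 * n_synergies <= n_muscles) {
      matrix(sample.int(n_muscles, 2 * n_synergies), nrow = 2)
    } else {
      vapply(seq_len(n_synergies), function(k) sample.int(n_muscles, 2),
             integer(2))
    }
    W[] <- stats::runif(n_muscles * n_synergies, 0, 0.04)
    leftover <- setdiff(seq_len(n_muscles), as.integer(exclusive))
    if (length(leftover)) {
      # at most one shared muscle per synergy, so no synergy grows wide
      # enough to be splittable into sub-groups
      hosts <- sample.int(n_synergies)[seq_len(min(length(leftover),
                                                   n_synergies))]
      for (i in seq_along(leftover)) {
        h <- hosts[((i - 1L) %% length(hosts)) + 1L]
        W[leftover[i], h] <- stats::runif(1, 0.25, 0.4)
      }
    }
    for (k in seq_len(n_synergies)) {
      W[exclusive[, k], k] <- stats::runif(2, 0.6, 1)
      W[, k] <- W[, k] / sqrt(sum(W[, k]^2))
    }
    }
    if (is.null(preferred_dir_deg)) {
      offs <- stats::runif(1, 0, 360 / n_synergies)
      preferred_dir_deg <- wrap_deg(offs + (seq_len(n_synergies) - 1) * 360 / n_synergies)
    }
    amplitude <- amplitude %||% stats::runif(n_synergies, 0.8, 1.2)
    tuning_offset <- tuning_offset %||% rep(0.05, n_synergies)
  })
  if (any(amplitude <= 0)) stop_emg("amplitude must be > 0", class = "emg_invalid")
  if (any(tuning_offset < 0)) stop_emg("tuning_offset must be >= 0", class = "emg_invalid")
  structure(
    list(W_true = W, preferred_dir_deg = as.numeric(preferred_dir_deg),
         amplitude = as.numeric(amplitude),
         tuning_offset = as.numeric(tuning_offset),
         envelope_params = envelope_params, snr = snr, seed = as.integer(seed),
         muscles = muscle_set(muscles)),
    class = "ground_truth"
  )
}

#' Rectified-cosine directional tuning
#'
#' Activation gain of a synergy toward a target direction:
#' `offset + amplitude * max(0, cos(direction - preferred))`. The rectified
#' cosine is the minimal unimodal nonnegative tuning law consistent with
#' direction-tuned, non-negative synergy activations.
#'
#' @param preferred_dir_deg Preferred direction (degrees).
#' @param amplitude Tuning gain (> 0 for a tuned synergy).
#' @param offset Direction-independent baseline (>= 0).
#' @param direction_deg Target direction (degrees); vectorized.
#' @return Nonnegative activation gain(s).
#' @export
tuning_value <- function(preferred_dir_deg, amplitude, offset, direction_deg) {
  offset + amplitude * pmax(0, cospi((direction_deg - preferred_dir_deg) / 180))
}

# unit-variance envelope-band (low-pass < 9 Hz) Gaussian noise, per muscle;
# uses the caller's RNG stream
smooth_noise <- function(dims, fs) {
  bf <- signal::butter(2, min(9 / (fs / 2), 0.99), type = "low")
  G <- matrix(stats::rnorm(prod(dims)), dims[1], dims[2])
  for (m in seq_len(dims[1])) {
    g <- signal::filtfilt(bf, G[m, ])
    G[m, ] <- g / stats::sd(g)
  }
  G
}

# minimum-jerk speed profile on tau in [0,1], peak scaled to v_peak
min_jerk_speed <- function(tau, v_peak = 1) {
  v <- 30 * tau^2 * (1 - tau)^2
  v[tau < 0 | tau > 1] <- 0
  v / 1.875 * v_peak # 30 * 0.5^2 * 0.5^2 = 1.875 at the midpoint
}

# task-specific activation envelope evaluated at times t (seconds)
task_envelope <- function(t, task, ep) {
  if (task == "isometric") {
    p <- ep$isometric
    on <- p$baseline_s + p$delay_s
    env <- pmin(1, pmax(0, (t - on) / p$ramp_s))
  } else {
    p <- ep$reaching
    center <- p$move_onset_s + p$move_dur_s / 2 - p$burst_lead_s
    env <- exp(-(t - center)^2 / (2 * p$burst_width_s^2))
    env[t < p$baseline_s] <- 0
  }
  env
}

#' Synthesize one EMG trial from a ground-truth model
#'
#' The clean EMG is `W_true %*% C_true` where
#' `C_true[k, t] = tuning_value(k, direction) * envelope(t)`; the envelope is
#' a ramp-and-hold trapezoid (isometric) or a Gaussian burst (reaching)
#' preceded by a rest baseline. Smooth (< 5 Hz) Gaussian envelope
#' variability is added -- per muscle, scaled to the muscle's active-window
#' RMS over `sqrt(snr)` and gated by the task envelope so the rest baseline
#' stays quiet -- plus a small ungated floor (1% of peak); the result is
#' clipped at zero. The auxiliary trace is a planar force ramp along
#' the target direction (isometric, 20 Hz) or a minimum-jerk hand-speed
#' profile (reaching, 1 kHz), with a small additive noise floor.
#'
#' The generative truth needed by oracle tests is attached as `$truth`:
#' the noiseless EMG, `C_true`, and the onset/offset events that the
#' published detection rules would find on the noiseless auxiliary trace
#' (force-ramp start for isometric; 10% peak-speed crossings for reaching),
#' on the EMG timebase.
#'
#' @param gt A [make_ground_truth()] object.
#' @param meta A [trial_meta()]; the direction must lie on the 12-target grid.
#' @param fs_emg EMG rate (Hz, default 1000).
#' @param fs_aux Auxiliary rate; defaults to 20 Hz (isometric) / 1000 Hz
#'   (reaching).
#' @param seed Integer seed for the trial's noise.
#' @param raw If `TRUE`, emit a signed interference-pattern signal (the
#'   envelope amplitude-modulating a band-limited zero-mean carrier) instead
#'   of the envelope-domain signal; used to exercise rectification and
#'   low-pass filtering.
#' @return An [emg_trial()] with a `$truth` field.
#' @export
synthesize_trial <- function(gt, meta, fs_emg = 1000, fs_aux = NULL, seed = 1,
                             raw = FALSE) {
  stopifnot(inherits(gt, "ground_truth"), inherits(meta, "trial_meta"))
  if (meta$direction_deg %% 30 != 0) {
    stop_emg("direction %s is not on the 12-target grid", meta$direction_deg,
             class = "emg_protocol")
  }
  task <- meta$task
  ep <- gt$envelope_params
  fs_aux <- fs_aux %||% if (task == "isometric") 20 else 1000
  if (task == "isometric") {
    p <- ep$isometric
    trial_s <- p$baseline_s + p$delay_s + p$ramp_s + p$hold_s
    baseline_s <- p$baseline_s
  } else {
    p <- ep$reaching
    trial_s <- p$trial_s
    baseline_s <- p$baseline_s
  }
  n <- round(trial_s * fs_emg)
  t_emg <- (seq_len(n) - 1) / fs_emg
  env <- task_envelope(t_emg, task, ep)
  gains <- tuning_value(gt$preferred_dir_deg, gt$amplitude, gt$tuning_offset,
                        meta$direction_deg)
  # trial-to-trial motor variability: independent lognormal gain jitter per
  # synergy (~15% CV), part of the generative model and recorded in C_true
  gains <- gains * with_seed(seed + 2L,
                             exp(stats::rnorm(length(gains), 0, 0.15)))
  C_true <- outer(gains, env)
  rownames(C_true) <- colnames(gt$W_true)
  clean <- gt$W_true %*% C_true
  peak <- max(clean)
  emg <- with_seed(seed, {
    # activity-gated low-frequency (< 5 Hz) envelope variability: per-muscle
    # additive noise scaled to that muscle's active-window RMS over sqrt(snr)
    # and gated by the task envelope, so it survives the 10 Hz envelope
    # filter (realizing the nominal snr in the extracted envelopes) while
    # the rest baseline stays quiet; plus a small ungated floor (1% of
    # peak); snr = Inf means a strictly noiseless trial
    x <- if (is.finite(gt$snr)) {
      G1 <- smooth_noise(dim(clean), fs_emg)
      G2 <- smooth_noise(dim(clean), fs_emg)
      gate <- env / max(env)                   # noise appears with activity
      active <- env > 0.1 * max(env)
      # per-muscle noise SD at full activation = active-window envelope RMS
      # over sqrt(snr); the activity gate scales it down with the envelope
      rms_m <- sqrt(rowMeans(clean[, active, drop = FALSE]^2))
      clean + (rms_m / sqrt(gt$snr)) * G1 * rep(gate, each = nrow(clean)) +
        0.01 * peak * G2
    } else {
      clean
    }
    if (raw) {
      # amplitude-modulated band-limited carrier: signed, zero-mean
      carrier <- matrix(stats::rnorm(length(clean)), nrow(clean))
      bf <- signal::butter(2, c(20, 450) / (fs_emg / 2), type = "pass")
      for (m in seq_len(nrow(carrier))) {
        carrier[m, ] <- signal::filtfilt(bf, carrier[m, ])
        carrier[m, ] <- carrier[m, ] / stats::sd(carrier[m, ])
      }
      pmax(x, 0) * carrier
    } else {
      pmax(x, 0)
    }
  })
  dimnames(emg) <- dimnames(clean)

  n_aux <- round(trial_s * fs_aux)
  t_aux <- (seq_len(n_aux) - 1) / fs_aux
  if (task == "isometric") {
    f_peak <- 10 # newtons, 40% of a typical maximum lateral force
    mag <- f_peak * task_envelope(t_aux, task, ep)
    theta <- meta$direction_deg * pi / 180
    aux_clean <- cbind(Fx = mag * cos(theta), Fy = mag * sin(theta), Fz = 0)
    aux <- if (is.finite(gt$snr)) {
      with_seed(seed + 1L, aux_clean + matrix(stats::rnorm(3 * n_aux,
                sd = 0.01 * f_peak), n_aux, 3))
    } else {
      aux_clean
    }
    colnames(aux) <- c("Fx", "Fy", "Fz")
    onset_t <- p$baseline_s + p$delay_s # force ramp start
    true_onset_aux <- which(t_aux >= onset_t)[1]
    true_onset <- round((true_onset_aux - 1) / fs_aux * fs_emg) + 1L
    true_offset <- n + 1L # isometric trials are trimmed to trial end
  } else {
    v_peak <- 0.5 # m/s
    tau <- (t_aux - p$move_onset_s) / p$move_dur_s
    v_clean <- min_jerk_speed(tau, v_peak)
    aux <- if (is.finite(gt$snr)) {
      with_seed(seed + 1L,
                pmax(0, v_clean + stats::rnorm(n_aux, sd = 0.002 * v_peak)))
    } else {
      v_clean
    }
    # events the 10%-of-peak rule finds on the noiseless profile
    thr <- 0.10 * max(v_clean)
    true_onset_aux <- which(v_clean > thr)[1]
    pk <- which.max(v_clean)
    after <- which(v_clean[(pk + 1):n_aux] < thr)
    true_offset_aux <- if (length(after)) pk + after[1] else n_aux + 1L
    true_onset <- round((true_onset_aux - 1) / fs_aux * fs_emg) + 1L
    true_offset <- round((true_offset_aux - 1) / fs_aux * fs_emg) + 1L
  }

  trial <- emg_trial(emg = emg, fs_emg = fs_emg, aux = aux, fs_aux = fs_aux,
                     baseline_window = c(1L, round(baseline_s * fs_emg) + 1L),
                     meta = meta, muscles = gt$muscles)
  trial$truth <- list(C_true = C_true, clean = clean,
                      onset_sample = as.integer(true_onset),
                      offset_sample = as.integer(if (task == "isometric")
                        true_offset else true_offset),
                      gains = gains, seed = as.integer(seed))
  trial
}

#' Synthesize a full condition dataset
#'
#' One condition = 12 target directions x `n_reps` repetitions at a single
#' task, starting location and participant. Per-trial seeds are derived from
#' the master seed by a counter-based splitting rule, so the dataset is
#' reproducible as a whole while trials are mutually independent.
#'
#' @param gt A [make_ground_truth()].
#' @param task `"isometric"` or `"reaching"`.
#' @param location Starting location label.
#' @param n_reps Repetitions per direction (default 5).
#' @param participant Participant id.
#' @param seed Master seed.
#' @param fs_emg,fs_aux Sampling rates, passed to [synthesize_trial()].
#' @param raw Passed to [synthesize_trial()].
#' @return An [emg_dataset()] of `12 * n_reps` trials.
#' @export
synthesize_dataset <- function(gt, task, location, n_reps = 5,
                               participant = "S1", seed = 1,
                               fs_emg = 1000, fs_aux = NULL, raw = FALSE) {
  if (n_reps < 1) stop_emg("n_reps must be >= 1", class = "emg_invalid")
  dirs <- target_directions()
  trials <- vector("list", length(dirs) * n_reps)
  i <- 0L
  for (d in dirs) {
    for (r in seq_len(n_reps)) {
      i <- i + 1L
      meta <- trial_meta(task = task, location = location, direction_deg = d,
                        rep = r, participant = participant)
      trials[[i]] <- synthesize_trial(gt, meta, fs_emg = fs_emg,
                                      fs_aux = fs_aux,
                                      seed = derive_seed(seed, i), raw = raw)
    }
  }
  emg_dataset(trials, gt$muscles)
}

#' Add a periodic ECG artifact to selected channels
#'
#' Adds a biphasic spike template (derivative-of-Gaussian, ~60 ms support)
#' at a fixed cardiac rate to a subset of channels, by default the trunk
#' muscles closest to the heart (PECT, UT, MT, LT). The spike train phase is
#' seeded; `floor(duration * rate_hz)` spikes always fit in the trial. The
#' added artifact is stored in `$ecg_artifact` so the original trial is
#' recoverable by subtraction.
#'
#' @param trial An [emg_trial()].
#' @param rate_hz Cardiac rate (default 1.2 Hz, i.e. 72 bpm).
#' @param amplitude Peak artifact amplitude in EMG units (>= 0).
#' @param channels Channel labels to contaminate.
#' @param seed Seed for the spike-train phase.
#' @return The trial with the artifact added and recorded.
#' @export
add_ecg_artifact <- function(trial, rate_hz = 1.2, amplitude = 0.5,
                             channels = c("PECT", "UT", "MT", "LT"),
                             seed = 1) {
  stopifnot(inherits(trial, "emg_trial"))
  if (amplitude < 0) stop_emg("amplitude must be >= 0", class = "emg_invalid")
  n <- ncol(trial$emg)
  fs <- trial$fs_emg
  dur <- n / fs
  n_spikes <- floor(dur * rate_hz)
  channels <- intersect(channels, rownames(trial$emg))
  art <- matrix(0, nrow(trial$emg), n, dimnames = dimnames(trial$emg))
  centers <- numeric(0)
  if (amplitude > 0 && n_spikes > 0 && length(channels) > 0) {
    phase <- with_seed(seed, stats::runif(1))
    centers <- ((seq_len(n_spikes) - 1) + phase) / rate_hz
    sigma <- 0.010 # s; QRS-like width
    tt <- seq(-0.03, 0.03, by = 1 / fs)
    template <- -tt / sigma * exp(-tt^2 / (2 * sigma^2))
    template <- template / max(abs(template)) * amplitude
    spike <- numeric(n)
    for (ct in centers) {
      idx <- round(ct * fs) + seq_along(tt) - floor(length(tt) / 2)
      keep <- idx >= 1 & idx <= n
      spike[idx[keep]] <- spike[idx[keep]] + template[keep]
    }
    for (ch in channels) art[ch, ] <- spike
  }
  trial$emg <- trial$emg + art
  trial$ecg_artifact <- list(artifact = art, channels = channels,
                             centers_s = centers, rate_hz = rate_hz,
                             amplitude = amplitude)
  trial
}
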