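#' Default muscle montage
#'
#' The 13 arm, shoulder and back muscles recorded in the center-out
#' experiments: brachioradialis (BRD), biceps (BI), brachialis (BRCH),
#' triceps long and lateral heads (TriLong, TriLat), anterior/middle/posterior
#' deltoid (AD, MD, PD), clavicular pectoralis (PECT), upper/middle/lower
#' trapezius (UT, MT, LT) and infraspinatus (IN).
#'
#' @return Character vector of 13 muscle labels.
#' @export
default_muscles <- function() {
  c("BRD", "BI", "BRCH", "TriLong", "TriLat", "AD", "MD", "PD",
    "PECT", "UT", "MT", "LT", "IN")
}

#' Construct a muscle set
#'
#' @param names Ordered character vector of unique muscle labels (at least 2).
#' @return A `muscle_set` (character vector with class attribute).
#' @export
muscle_set <- function(names = default_muscles()) {
  names <- as.character(names)
  if (anyDuplicated(names)) {
    stop_emg("muscle names must be unique", class = "emg_invalid")
  }
  if (length(names) < 2L) {
    stop_emg("a muscle set needs at least 2 muscles", class = "emg_invalid")
  }
  structure(names, class = "muscle_set")
}

#' Canonical target directions (degrees)
#'
#' Twelve equispaced center-out targets, 30 degrees apart, counterclockwise
#' positive.
#' @return Numeric vector `seq(0, 330, by = 30)`.
#' @export
target_directions <- function() seq(0, 330, by = 30)

#' Per-trial metadata
#'
#' @param task `"isometric"` (force generation against a fixed handle) or
#'   `"reaching"` (point-to-point hand movement).
#' @param location Starting arm location: `"Distal"`, `"Left"`, `"Proximal"`
#'   or `"Right"`.
#' @param direction_deg Target direction in degrees; must lie on the
#'   12-target grid (a multiple of 30 in `[0, 360)`).
#' @param rep Repetition index, a positive integer.
#' @param participant Participant identifier.
#' @param excluded Logical flag for trials that failed all match attempts and
#'   should be dropped from analysis.
#' @return A `trial_meta` list.
#' @export
trial_meta <- function(task, location, direction_deg, rep = 1L,
                       participant = "P01", excluded = FALSE) {
  task <- match.arg(task, c("isometric", "reaching"))
  location <- match.arg(location, c("Distal", "Left", "Proximal", "Right"))
  direction_deg <- as.numeric(direction_deg)
  if (length(direction_deg) != 1L || is.na(direction_deg) ||
      direction_deg < 0 || direction_deg >= 360 || direction_deg %% 30 != 0) {
    stop_emg("direction_deg must be a multiple of 30 in [0, 360), got %s",
             format(direction_deg), class = "emg_invalid")
  }
  rep <- as.integer(rep)
  if (is.na(rep) || rep < 1L) stop_emg("rep must be >= 1", class = "emg_invalid")
  structure(
    list(task = task, location = location, direction_deg = direction_deg,
         rep = rep, participant = as.character(participant),
         excluded = isTRUE(excluded)),
    class = "trial_meta"
  )
}

#' Construct one EMG trial
#'
#' The atomic unit of the pipeline: a muscles-by-samples EMG matrix plus the
#' auxiliary end-point trace used for event detection (3-axis force for the
#' isometric task, scalar hand speed for reaching), the pre-cue baseline
#' window and the trial metadata.
#'
#' All sample intervals are half-open `[start, end)` with 1-based starts:
#' `baseline_window = c(1, 5001)` means EMG samples 1..5000. Event indices
#' are always reported on the EMG timebase.
#'
#' @param emg Numeric matrix, muscles x samples; row names are muscle labels.
#' @param fs_emg EMG sampling rate in Hz (default 1000).
#' @param aux Auxiliary trace: an n-by-3 matrix of forces `(Fx, Fy, Fz)` in
#'   newtons for isometric trials, or a nonnegative numeric vector of hand
#'   speed for reaching trials.
#' @param fs_aux Auxiliary sampling rate in Hz (20 for force, 1000 for speed
#'   by convention).
#' @param baseline_window Half-open interval `c(start, end)` of the rest
#'   period, on the EMG timebase.
#' @param events Optional list with `onset_sample` and `offset_sample`
#'   (half-open, EMG timebase).
#' @param meta A [trial_meta()].
#' @param muscles A [muscle_set()]; defaults to the EMG row names.
#' @return An `emg_trial` list.
#' @export
emg_trial <- function(emg, fs_emg = 1000, aux, fs_aux,
                      baseline_window, events = NULL, meta,
                      muscles = NULL) {
  emg <- as.matrix(emg)
  if (is.null(muscles)) {
    if (is.null(rownames(emg))) {
      stop_emg("emg must have muscle row names or an explicit muscle set",
               class = "emg_invalid")
    }
    muscles <- muscle_set(rownames(emg))
  } else {
    muscles <- muscle_set(unclass(muscles))
  }
  if (nrow(emg) != length(muscles)) {
    stop_emg("emg has %d rows but the muscle set has %d muscles",
             nrow(emg), length(muscles), class = "emg_invalid")
  }
  rownames(emg) <- unclass(muscles)
  if (!is.numeric(fs_emg) || fs_emg <= 0) {
    stop_emg("fs_emg must be > 0", class = "emg_invalid")
  }
  if (!is.numeric(fs_aux) || fs_aux <= 0) {
    stop_emg("fs_aux must be > 0", class = "emg_invalid")
  }
  n <- ncol(emg)
  bw <- as.integer(baseline_window)
  if (length(bw) != 2L || bw[1] < 1L || bw[2] <= bw[1] || bw[1] > n) {
    stop_emg("baseline_window must be a nonempty half-open interval within the trial",
             class = "emg_invalid")
  }
  if (!is.null(events)) {
    if (!(events$onset_sample < events$offset_sample)) {
      stop_emg("onset_sample must precede offset_sample", class = "emg_invalid")
    }
    if (bw[2] > events$onset_sample) {
      stop_emg("baseline_window must precede the trial events", class = "emg_invalid")
    }
  }
  if (!inherits(meta, "trial_meta")) stop_emg("meta must be a trial_meta", class = "emg_invalid")
  structure(
    list(emg = emg, fs_emg = fs_emg, aux = aux, fs_aux = fs_aux,
         baseline_window = bw, events = events, meta = meta,
         muscles = muscles),
    class = "emg_trial"
  )
}

#' Bundle trials into a dataset
#'
#' All trials must share task, starting location and participant: a dataset
#' is one experimental condition, the unit on which synergies are extracted.
#'
#' @param trials List of [emg_trial()] objects.
#' @param muscles Optional [muscle_set()]; defaults to the first trial's.
#' @return An `emg_dataset` list with elements `trials` and `muscles`.
#' @export
emg_dataset <- function(trials, muscles = NULL) {
  if (length(trials) == 0L) stop_emg("a dataset needs at least one trial", class = "emg_invalid")
  if (!all(vapply(trials, inherits, logical(1), "emg_trial"))) {
    stop_emg("all elements of trials must be emg_trial objects", class = "emg_invalid")
  }
  muscles <- muscles %||% trials[[1]]$muscles
  muscles <- muscle_set(unclass(muscles))
  for (i in seq_along(trials)) {
    if (!identical(unclass(trials[[i]]$muscles), unclass(muscles))) {
      stop_emg("trial %d has a different muscle set than the dataset", i,
               class = "emg_inconsistent")
    }
  }
  key <- vapply(trials, function(tr) {
    paste(tr$meta$task, tr$meta$location, tr$meta$participant, sep = "/")
  }, character(1))
  if (length(unique(key)) != 1L) {
    stop_emg("all trials in a dataset must share task, location and participant",
             class = "emg_inconsistent")
  }
  structure(list(trials = trials, muscles = muscles), class = "emg_dataset")
}

#' @export
print.emg_dataset <- function(x, ...) {
  m <- x$trials[[1]]$meta
  cat(sprintf("<emg_dataset> %d trials | task=%s location=%s participant=%s | %d muscles\n",
              length(x$trials), m$task, m$location, m$participant,
              length(x$muscles)))
  invisible(x)
}

#' Pipeline configuration with defaults
#'
#' Collects every tunable of the pipeline in one nested list. Defaults follow
#' the published processing chain: 4th-order 10 Hz zero-phase Butterworth
#' envelope filter, 3 x SD force onset rule, 10% peak-speed movement onset
#' rule, 150-sample time normalization, per-muscle variance normalization,
#' 1000-draw permutation null at the 95th percentile, 5-point TOST margin,
#' and local-coordinate rotations of -28 deg (Left) and +22.4 deg (Right).
#'
#' @param ... Named overrides, e.g. `nnmf = list(restarts = 5)`. Overrides
#'   are merged recursively into the defaults.
#' @return A `pipeline_config` nested list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    filter = list(order = 4, cutoff_hz = 10),
    ecg = list(enabled = TRUE, levels = 6, k_mad = 4),
    resample_length = 150,
    onset = list(force_sd_mult = 3, speed_fraction = 0.10, guard_s = 0.5),
    normalize = "variance",
    nnmf = list(restarts = 20, max_iter = 1000, tol = 1e-6, seed = 1),
    order_selection = list(k_range = 1:10, gvaf_min = 90, delta_max = 5,
                           muscle_vaf_min = 60, delta_mode = "next"),
    permutation = list(n_random = 1000, percentile = 95, alpha = 0.05,
                       n_comparisons = 1, position_preserving = TRUE,
                       seed = 1),
    tost = list(margin = 5, alpha = 0.05),
    rotation = list(Distal = 0, Left = -28, Proximal = 0, Right = 22.4),
    tuning = list(aggregator = "mean")
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop_emg("pipeline_config overrides must be named", class = "emg_invalid")
    }
    cfg <- utils::modifyList(cfg, overrides)
  }
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  pos <- c(cfg$filter$order, cfg$filter$cutoff_hz, cfg$ecg$levels, cfg$ecg$k_mad,
           cfg$resample_length, cfg$onset$force_sd_mult, cfg$nnmf$restarts,
           cfg$nnmf$max_iter, cfg$nnmf$tol, cfg$permutation$n_random,
           cfg$tost$margin, cfg$tost$alpha)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop_emg("all numeric pipeline parameters must be strictly positive",
             class = "emg_invalid")
  }
  if (cfg$permutation$percentile <= 0 || cfg$permutation$percentile >= 100) {
    stop_emg("permutation percentile must lie in (0, 100)", class = "emg_invalid")
  }
  if (!cfg$normalize %in% c("variance", "sd")) {
    stop_emg("normalize must be 'variance' or 'sd'", class = "emg_invalid")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror [pipeline_config()]; missing keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}
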