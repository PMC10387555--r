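#' Rotate a target direction into local coordinates
#'
#' Aligns the biomechanical forward/backward axes across starting arm
#' locations: the Left location is rotated 28 degrees clockwise, the Right
#' location 22.4 degrees counterclockwise, Distal and Proximal are
#' unchanged. The rotation angles are cohort geometry, configurable per
#' location.
#'
#' @param direction_deg Angle(s) in degrees (counterclockwise positive).
#' @param location `"Distal"`, `"Left"`, `"Proximal"` or `"Right"`.
#' @param rotation Named list of per-location rotation angles (degrees,
#'   added to the input); defaults to the standard geometry.
#' @return Local angle(s) wrapped to `[0, 360)`.
#' @export
rotate_to_local <- function(direction_deg, location,
                            rotation = pipeline_config()$rotation) {
  if (!location %in% names(rotation)) {
    stop_emg("no rotation configured for location '%s'", location,
             class = "emg_config")
  }
  wrap_deg(direction_deg + rotation[[location]])
}

#' Direction-tuning curve of synergy activations
#'
#' For each synergy and each of the 12 target directions (expressed in
#' local coordinates), the mean activation magnitude over all samples of
#' all trials toward that direction. A `"peak"` aggregator (per-trial peak
#' activation, averaged over trials) is available via `aggregator`.
#'
#' @param C An `activation_set` whose columns carry direction labels.
#' @param location Starting location used for the local-coordinate rotation.
#' @param rotation Per-location rotation angles (see [rotate_to_local()]).
#' @param aggregator `"mean"` (default) or `"peak"`.
#' @return A `tuning_curve` list: `values` (K x 12), `directions_deg`
#'   (the 12 local angles, ascending), `n_trials` per direction.
#' @export
compute_tuning_curve <- function(C, location,
                                 rotation = pipeline_config()$rotation,
                                 aggregator = c("mean", "peak")) {
  stopifnot(inherits(C, "activation_set"))
  aggregator <- match.arg(aggregator)
  if (is.null(C$direction_deg)) {
    stop_emg("activation set has no direction labels", class = "emg_invalid")
  }
  local_dir <- rotate_to_local(C$direction_deg, location, rotation)
  grid <- sort(unique(rotate_to_local(target_directions(), location, rotation)))
  missing <- setdiff(grid, unique(local_dir))
  if (length(missing)) {
    stop_emg("no trials toward local direction(s): %s",
             paste(format(missing), collapse = ", "),
             class = "emg_missing_direction")
  }
  K <- nrow(C$C)
  values <- matrix(0, K, length(grid),
                   dimnames = list(rownames(C$C), format(grid)))
  n_trials <- integer(length(grid))
  for (j in seq_along(grid)) {
    cols <- which(local_dir == grid[j])
    n_trials[j] <- length(unique(C$trial_index[cols] %||% cols))
    if (aggregator == "mean") {
      values[, j] <- rowMeans(C$C[, cols, drop = FALSE])
    } else {
      tr <- C$trial_index[cols]
      peaks <- vapply(unique(tr), function(id) {
        apply(C$C[, cols[tr == id], drop = FALSE], 1, max)
      }, numeric(K))
      values[, j] <- rowMeans(matrix(peaks, nrow = K))
    }
  }
  structure(
    list(values = values, directions_deg = grid, n_trials = n_trials,
         location = location),
    class = "tuning_curve"
  )
}

#' Tuning direction of a synergy's direction curve
#'
#' The angle of the linear (vector) summation of the curve's components,
#' `sum_j v_j (cos t_j, sin t_j)`; the resultant length is the norm of that
#' sum (zero for an untuned, e.g. uniform or perfectly opposing, curve).
#'
#' @param values Nonnegative activation means, one per direction; or a
#'   `tuning_curve` (every synergy is summarized).
#' @param directions_deg Directions matching `values` (ignored when a
#'   `tuning_curve` is given).
#' @param eps_frac Untuned flag threshold: resultant lengths below
#'   `eps_frac * sum(values)` are flagged (default 1e-9).
#' @return A `tuning_direction` data frame: `angle_deg`,
#'   `resultant_length`, `untuned` (one row per synergy).
#' @export
tuning_direction <- function(values, directions_deg = NULL, eps_frac = 1e-9) {
  if (inherits(values, "tuning_curve")) {
    directions_deg <- values$directions_deg
    values <- values$values
  }
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  stopifnot(ncol(values) == length(directions_deg))
  th <- directions_deg * pi / 180
  vx <- as.numeric(values %*% cos(th))
  vy <- as.numeric(values %*% sin(th))
  R <- sqrt(vx^2 + vy^2)
  ang <- wrap_deg(atan2(vy, vx) * 180 / pi)
  untuned <- R < eps_frac * rowSums(values) | rowSums(values) == 0
  ang[untuned] <- NA_real_
  structure(
    data.frame(angle_deg = ang, resultant_length = R, untuned = untuned),
    class = c("tuning_direction", "data.frame")
  )
}

#' Change-point activation threshold
#'
#' Sorts the pooled activation magnitudes (all synergies, trials and
#' participants of one location x task) in ascending order and finds the
#' single split that minimizes the summed segment cost, where a segment's
#' cost is its length times its variance (equivalently its sum of squared
#' deviations from the segment mean) -- the point where the variance of the
#' sorted sequence changes abruptly. The threshold is the first value of
#' the upper segment; activation counts are strict exceedances of it.
#'
#' The search is exhaustive over all splits, computed in O(n) with prefix
#' sums, and deterministic (first minimizing split on ties).
#'
#' @param pooled Nonnegative activation magnitudes.
#' @return An `activation_threshold` list: `t`, `change_index` (last index
#'   of the lower segment in the sorted sequence), `n`, `cost`.
#' @export
activation_threshold <- function(pooled) {
  x <- sort(as.numeric(pooled))
  n <- length(x)
  if (n < 2L) stop_emg("need at least 2 pooled values", class = "emg_invalid")
  if (max(x) - min(x) <= 0) {
    stop_emg("constant activation sequence: no change point exists",
             class = "emg_no_change_point")
  }
  s1 <- cumsum(x); s2 <- cumsum(x^2)
  seg_cost_left <- s2[1:(n - 1)] - s1[1:(n - 1)]^2 / (1:(n - 1))
  s1r <- s1[n] - s1[1:(n - 1)]
  s2r <- s2[n] - s2[1:(n - 1)]
  seg_cost_right <- s2r - s1r^2 / ((n - 1):1)
  cost <- seg_cost_left + seg_cost_right
  j <- which.min(cost)
  structure(
    list(t = x[j + 1L], change_index = j, n = n, cost = cost[j]),
    class = "activation_threshold"
  )
}

#' Count synergies active per target direction
#'
#' A synergy counts as active toward a direction when its tuning-curve cell
#' strictly exceeds the change-point activation threshold.
#'
#' @param curve A [compute_tuning_curve()] result.
#' @param threshold An [activation_threshold()] result or a bare number.
#' @return Named integer vector of counts (0..K), one per direction.
#' @export
count_active_synergies <- function(curve, threshold) {
  stopifnot(inherits(curve, "tuning_curve"))
  t0 <- if (inherits(threshold, "activation_threshold")) threshold$t else threshold
  counts <- colSums(curve$values > t0)
  stats::setNames(as.integer(counts), colnames(curve$values))
}
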