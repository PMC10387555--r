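#' Construct a synergy set
#'
#' A nonnegative muscles-by-K weight matrix with unit-Euclidean-norm
#' columns: each column is one muscle synergy.
#'
#' @param W Nonnegative numeric matrix (muscles x K) with muscle row names.
#' @param muscles Optional [muscle_set()]; defaults to the row names.
#' @param normalize If `TRUE` (default), columns are renormalized to unit
#'   norm; if `FALSE`, unit norm is asserted.
#' @return A `synergy_set` list with fields `W`, `muscles`, `k`.
#' @export
synergy_set <- function(W, muscles = NULL, normalize = TRUE) {
  W <- as.matrix(W)
  if (any(W < 0)) stop_emg("synergy weights must be nonnegative", class = "emg_invalid")
  muscles <- muscles %||% muscle_set(rownames(W))
  nrm <- sqrt(colSums(W^2))
  if (normalize) {
    nz <- nrm > 0
    W[, nz] <- sweep(W[, nz, drop = FALSE], 2, nrm[nz], "/")
  } else if (any(abs(nrm - 1) > 1e-8)) {
    stop_emg("synergy columns must have unit Euclidean norm", class = "emg_invalid")
  }
  rownames(W) <- unclass(muscles)
  if (is.null(colnames(W))) colnames(W) <- sprintf("syn%d", seq_len(ncol(W)))
  structure(list(W = W, muscles = muscles, k = ncol(W)), class = "synergy_set")
}

#' Construct an activation set
#'
#' The K-by-samples nonnegative activation matrix paired with the pooled
#' matrix's per-column trial and direction bookkeeping.
#'
#' @param C Nonnegative numeric matrix (K x pooled samples).
#' @param trial_index,direction_deg Optional per-column labels.
#' @return An `activation_set` list.
#' @export
activation_set <- function(C, trial_index = NULL, direction_deg = NULL) {
  C <- as.matrix(C)
  if (any(C < 0)) stop_emg("activations must be nonnegative", class = "emg_invalid")
  if (!is.null(direction_deg) && length(direction_deg) != ncol(C)) {
    stop_emg("direction labels must match the activation columns", class = "emg_invalid")
  }
  structure(list(C = C, trial_index = trial_index,
                 direction_deg = direction_deg), class = "activation_set")
}

as_pooled_matrix <- function(E) {
  if (inherits(E, "pooled_emg")) E$matrix else as.matrix(E)
}

#' Variance accounted for by a synergy reconstruction
#'
#' `VAF = 100 * (1 - SSE / SST)` where SSE is the sum of squared residuals
#' of `E - W %*% C` and SST is the *uncentered* sum of squared data.
#' The global value pools all entries; per-muscle values restrict SSE and
#' SST to one muscle's row.
#'
#' @param E Data matrix or `pooled_emg`.
#' @param W Synergy matrix or `synergy_set`.
#' @param C Activation matrix or `activation_set`.
#' @return A `vaf_entry` list: `gvaf`, `per_muscle_vaf`, `sse`, `sst`.
#' @export
vaf <- function(E, W, C) {
  E <- as_pooled_matrix(E)
  if (inherits(W, "synergy_set")) W <- W$W
  if (inherits(C, "activation_set")) C <- C$C
  resid <- E - W %*% C
  sst_m <- rowSums(E^2)
  sse_m <- rowSums(resid^2)
  sst <- sum(sst_m)
  if (sst <= 0) stop_emg("SST is zero: degenerate input", class = "emg_degenerate")
  per_muscle <- 100 * (1 - sse_m / sst_m)
  names(per_muscle) <- rownames(E)
  structure(
    list(gvaf = 100 * (1 - sum(sse_m) / sst), per_muscle_vaf = per_muscle,
         sse = sum(sse_m), sst = sst),
    class = "vaf_entry"
  )
}

# Nonnegative double SVD initialization (Boutsidis & Gallopoulos): split each
# leading singular vector pair into its positive and negative parts and keep
# the dominant pair; zeros are backfilled with the matrix mean so
# multiplicative updates can move every entry.
nndsvd_init <- function(E, k) {
  sv <- svd(E, nu = k, nv = k)
  W <- matrix(0, nrow(E), k)
  C <- matrix(0, k, ncol(E))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  C[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
      nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
      if (npos >= nneg && npos > 0) {
        W[, j] <- sqrt(sv$d[j] * npos) * up / sqrt(sum(up^2))
        C[j, ] <- sqrt(sv$d[j] * npos) * vp / sqrt(sum(vp^2))
      } else if (nneg > 0) {
        W[, j] <- sqrt(sv$d[j] * nneg) * un / sqrt(sum(un^2))
        C[j, ] <- sqrt(sv$d[j] * nneg) * vn / sqrt(sum(vn^2))
      }
    }
  }
  fill <- mean(E)
  W[W < fill * 1e-4] <- fill * 1e-4
  C[C < fill * 1e-4] <- fill * 1e-4
  list(W = W, C = C)
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a nonnegative pooled EMG matrix `E ~ W %*% C` at a fixed model
#' order `k`, minimizing the squared Frobenius reconstruction error with
#' Lee-Seung multiplicative updates. The factorization is repeated from
#' `restarts` random initializations and the solution with the lowest final
#' SSE is kept; columns of `W` are then renormalized to unit norm with a
#' compensating rescale of `C`, which leaves `W %*% C` unchanged. The run is
#' deterministic for a fixed seed.
#'
#' @param E Nonnegative matrix or `pooled_emg`.
#' @param k Model order (`1 <= k <= min(dim(E))`).
#' @param restarts Random restarts (default 20).
#' @param max_iter Maximum update iterations per restart (default 1000).
#' @param tol Relative SSE change declaring convergence (default 1e-6);
#'   checked every 10 iterations.
#' @param seed RNG seed.
#' @return An `nnmf_fit` list: `W` (`synergy_set`), `C` (`activation_set`),
#'   `sse`, `vaf` (a [vaf()] entry), `k`, `seed`, `sse_trace` (SSE at each
#'   convergence check of the winning restart).
#' @export
nnmf <- function(E, k, restarts = 20, max_iter = 1000, tol = 1e-6, seed = 1) {
  pooled <- if (inherits(E, "pooled_emg")) E else NULL
  E <- as_pooled_matrix(E)
  if (any(!is.finite(E))) stop_emg("E contains non-finite entries", class = "emg_input")
  if (any(E < 0)) stop_emg("E must be nonnegative", class = "emg_input")
  if (k < 1 || k > min(dim(E))) {
    stop_emg("model order %d outside [1, %d]", k, min(dim(E)), class = "emg_order")
  }
  eps <- 1e-12
  best <- NULL
  init0 <- nndsvd_init(E, k)
  for (r in seq_len(restarts)) {
    fit <- with_seed(derive_seed(seed, r), {
      scale0 <- sqrt(mean(E) / k)
      if (r == 1L) {
        # deterministic SVD-based start; lands near the dominant nonnegative
        # structure and reduces dependence on random restarts
        W <- init0$W
        C <- init0$C
      } else {
        W <- matrix(stats::runif(nrow(E) * k, 0.1, 1) * scale0, nrow(E), k)
        C <- matrix(stats::runif(k * ncol(E), 0.1, 1) * scale0, k, ncol(E))
      }
      sse_prev <- Inf
      trace <- numeric(0)
      for (it in seq_len(max_iter)) {
        C <- C * (crossprod(W, E) / (crossprod(W, W %*% C) + eps))
        W <- W * (tcrossprod(E, C) / (W %*% tcrossprod(C, C) + eps))
        if (it %% 10 == 0 || it == max_iter) {
          sse <- sum((E - W %*% C)^2)
          trace <- c(trace, sse)
          if (is.finite(sse_prev) && (sse_prev - sse) <= tol * sse_prev) break
          sse_prev <- sse
        }
      }
      list(W = W, C = C, sse = sum((E - W %*% C)^2), trace = trace)
    })
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  nrm <- sqrt(colSums(best$W^2))
  nz <- nrm > 0
  best$W[, nz] <- sweep(best$W[, nz, drop = FALSE], 2, nrm[nz], "/")
  best$C[nz, ] <- best$C[nz, , drop = FALSE] * nrm[nz]
  rownames(best$W) <- rownames(E)
  ms <- if (!is.null(pooled)) pooled$muscles else muscle_set(rownames(E) %||%
        sprintf("M%02d", seq_len(nrow(E))))
  W_set <- synergy_set(best$W, muscles = ms, normalize = FALSE)
  C_set <- activation_set(pmax(best$C, 0),
                          trial_index = pooled$trial_index,
                          direction_deg = pooled$direction_deg)
  v <- vaf(E, W_set$W, C_set$C)
  structure(
    list(W = W_set, C = C_set, sse = best$sse, vaf = v, k = k,
         seed = as.integer(seed), sse_trace = best$trace),
    class = "nnmf_fit"
  )
}

#' Map synergies back to raw EMG units
#'
#' Synergies are extracted from the variance-normalized pooled matrix, so
#' their weights live in normalized units. Multiplying each muscle row by
#' its stored normalization divisor (and renormalizing columns) expresses
#' the synergies on the original envelope scale, which is the scale of a
#' generative ground-truth `W_true`.
#'
#' @param W A `synergy_set` extracted from `pooled`.
#' @param pooled The `pooled_emg` the set was extracted from.
#' @return A `synergy_set` in raw units.
#' @export
denormalize_synergies <- function(W, pooled) {
  stopifnot(inherits(W, "synergy_set"), inherits(pooled, "pooled_emg"))
  synergy_set(W$W * pooled$muscle_variances, muscles = W$muscles)
}

#' Select the number of synergies from the VAF criteria
#'
#' Scans candidate model orders in ascending order and selects the smallest
#' `k` that jointly satisfies the three criteria: global VAF above
#' `gvaf_min` (90%), the global VAF gain from adding one more synergy below
#' `delta_max` (5 points), and every muscle's VAF above `muscle_vaf_min`
#' (60%). If no candidate qualifies the decision is an explicit no-solution
#' outcome (`selected_k = NA`), never a silent default. The full criteria
#' trace is returned for audit.
#'
#' The delta criterion direction is configurable: `delta_mode = "next"`
#' (default) reads it as `gvaf(k+1) - gvaf(k) < delta_max`; `"prev"` as
#' `gvaf(k) - gvaf(k-1) < delta_max`.
#'
#' @param E Nonnegative matrix or `pooled_emg`.
#' @param k_range Candidate orders (default from `config`).
#' @param config A [pipeline_config()]; `nnmf` and `order_selection` entries
#'   are used.
#' @return A `model_order_decision` list: `selected_k`, `criteria_trace`
#'   (data frame with gvaf, delta, min muscle VAF and the three booleans per
#'   k), `fits` (the `nnmf_fit` for each evaluated k), `no_solution`.
#' @export
select_model_order <- function(E, k_range = NULL, config = pipeline_config()) {
  os <- config$order_selection
  k_range <- sort(unique(as.integer(k_range %||% os$k_range)))
  Emat <- as_pooled_matrix(E)
  k_max_allowed <- min(dim(Emat))
  k_range <- k_range[k_range >= 1 & k_range <= k_max_allowed]
  if (length(k_range) == 0L) stop_emg("empty candidate order range", class = "emg_order")
  fits <- list()
  get_fit <- function(k) {
    key <- as.character(k)
    if (is.null(fits[[key]])) {
      fits[[key]] <<- nnmf(E, k, restarts = config$nnmf$restarts,
                           max_iter = config$nnmf$max_iter,
                           tol = config$nnmf$tol,
                           seed = derive_seed(config$nnmf$seed, k))
    }
    fits[[key]]
  }
  rows <- list()
  selected <- NA_integer_
  for (k in k_range) {
    fit <- get_fit(k)
    g <- fit$vaf$gvaf
    if (identical(os$delta_mode, "prev")) {
      delta <- if (k - 1 >= 1) g - get_fit(k - 1)$vaf$gvaf else NA_real_
    } else {
      delta <- if (k + 1 <= k_max_allowed) get_fit(k + 1)$vaf$gvaf - g else NA_real_
    }
    mv <- min(fit$vaf$per_muscle_vaf)
    c1 <- g > os$gvaf_min
    c2 <- is.na(delta) || delta < os$delta_max
    c3 <- mv > os$muscle_vaf_min
    rows[[length(rows) + 1L]] <- data.frame(
      k = k, gvaf = g, delta_gvaf = delta, min_muscle_vaf = mv,
      gvaf_ok = c1, delta_ok = c2, muscle_vaf_ok = c3,
      pass = c1 && c2 && c3
    )
    if (is.na(selected) && c1 && c2 && c3) {
      selected <- k
      break # smallest qualifying order; later k need not be fitted
    }
  }
  structure(
    list(selected_k = selected, criteria_trace = do.call(rbind, rows),
         fits = fits, no_solution = is.na(selected)),
    class = "model_order_decision"
  )
}

#' @export
print.model_order_decision <- function(x, ...) {
  if (x$no_solution) {
    cat("<model_order_decision> no order satisfied all three VAF criteria\n")
  } else {
    cat(sprintf("<model_order_decision> selected_k = %d\n", x$selected_k))
  }
  print(x$criteria_trace, row.names = FALSE)
  invisible(x)
}
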