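#' Scalar-product similarity of two synergy vectors
#'
#' Dot product of the unit-normalized vectors; symmetric, invariant to
#' positive rescaling, and in `[0, 1]` for nonnegative vectors.
#'
#' @param w1,w2 Nonnegative numeric vectors of equal length.
#' @return Similarity r in `[0, 1]`.
#' @export
similarity <- function(w1, w2) {
  stopifnot(length(w1) == length(w2))
  n1 <- sqrt(sum(w1^2)); n2 <- sqrt(sum(w2^2))
  if (n1 == 0 || n2 == 0) {
    stop_emg("similarity is undefined for a zero vector", class = "emg_zero_vector")
  }
  min(1, sum(w1 * w2) / (n1 * n2))
}

# all injective assignments of seq_len(ka) into seq_len(kb), ka <= kb
injective_assignments <- function(ka, kb) {
  per <- pracma::perms(seq_len(kb)) # each row a permutation of 1..kb
  asg <- unique(per[, seq_len(ka), drop = FALSE])
  asg[do.call(order, as.data.frame(asg)), , drop = FALSE]
}

#' Match two synergy sets one-to-one
#'
#' Pairs the synergies of two sets over `min(K_a, K_b)` pairs so that the
#' total scalar-product similarity is maximal (exhaustive search over
#' assignments, intended for K <= 8). Ties break deterministically toward
#' the lexicographically smallest assignment. A `"greedy"` method is
#' available that repeatedly takes the best remaining pair and removes it
#' from the pool (the sequential scheme used in the field); the two agree
#' on well-separated sets.
#'
#' @param Wa,Wb `synergy_set`s (or matrices) over the same ordered muscles.
#' @param method `"global"` (default) or `"greedy"`.
#' @return A `match_result` list: `pairs` (data frame `a`, `b`,
#'   `similarity`), `total_similarity`, `k_a`, `k_b`, `threshold` (NA until
#'   [apply_threshold()]), `significant`, `null_params`.
#' @export
match_synergies <- function(Wa, Wb, method = c("global", "greedy")) {
  method <- match.arg(method)
  ma <- if (inherits(Wa, "synergy_set")) Wa$W else as.matrix(Wa)
  mb <- if (inherits(Wb, "synergy_set")) Wb$W else as.matrix(Wb)
  if (!is.null(rownames(ma)) && !is.null(rownames(mb)) &&
      !identical(rownames(ma), rownames(mb))) {
    stop_emg("synergy sets are over different muscle orderings", class = "emg_alignment")
  }
  if (nrow(ma) != nrow(mb)) {
    stop_emg("synergy sets have different muscle counts", class = "emg_alignment")
  }
  S <- crossprod(sweep(ma, 2, sqrt(colSums(ma^2)), "/"),
                 sweep(mb, 2, sqrt(colSums(mb^2)), "/"))
  swapped <- FALSE
  if (nrow(S) > ncol(S)) { S <- t(S); swapped <- TRUE }
  ka <- nrow(S); kb <- ncol(S)
  if (method == "global") {
    asg <- injective_assignments(ka, kb)
    totals <- vapply(seq_len(nrow(asg)), function(i) {
      sum(S[cbind(seq_len(ka), asg[i, ])])
    }, numeric(1))
    pick <- asg[which.max(totals), ] # which.max: first (lexicographic) max
  } else {
    pick <- integer(ka)
    Sw <- S
    for (step in seq_len(ka)) {
      idx <- which(Sw == max(Sw, na.rm = TRUE), arr.ind = TRUE)[1, ]
      pick[idx[1]] <- idx[2]
      Sw[idx[1], ] <- NA
      Sw[, idx[2]] <- NA
    }
  }
  sims <- S[cbind(seq_len(ka), pick)]
  pairs <- if (swapped) {
    data.frame(a = pick, b = seq_len(ka), similarity = sims)
  } else {
    data.frame(a = seq_len(ka), b = pick, similarity = sims)
  }
  pairs <- pairs[order(pairs$a), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(
    list(pairs = pairs, total_similarity = sum(sims),
         k_a = if (swapped) kb else ka, k_b = if (swapped) ka else kb,
         threshold = NA_real_, significant = NULL, null_params = NULL),
    class = "match_result"
  )
}

#' Permutation-null similarity threshold
#'
#' Builds `n_random` random synergy vectors whose weight at each muscle
#' position is drawn (with replacement) from the pooled computed weights at
#' that position, unit-normalizes them, computes all
#' `n_random * (n_random - 1) / 2` pairwise scalar products, and returns the
#' stated percentile of the ascending list as the chance-level similarity
#' threshold. With a Bonferroni correction for `n_comparisons = m > 1`, the
#' percentile becomes `100 * (1 - alpha / m)`.
#'
#' @param pool Muscles-by-N matrix of computed synergy vectors from all
#'   conditions (or a list of `synergy_set`s, which are column-bound).
#' @param n_random Number of random vectors (default 1000).
#' @param percentile Uncorrected percentile (default 95).
#' @param alpha Significance level implied by the percentile (default 0.05).
#' @param n_comparisons Bonferroni divisor m (default 1 = no correction).
#' @param seed RNG seed; the threshold is bit-reproducible given the seed.
#' @param position_preserving If `FALSE`, weights are resampled from all
#'   positions pooled rather than per muscle position.
#' @return A `perm_threshold` list: `threshold`, `n_pairs`,
#'   `percentile_used`, `null_params`.
#' @export
permutation_threshold <- function(pool, n_random = 1000, percentile = 95,
                                  alpha = 0.05, n_comparisons = 1, seed = 1,
                                  position_preserving = TRUE) {
  if (is.list(pool) && !is.matrix(pool)) {
    pool <- do.call(cbind, lapply(pool, function(w)
      if (inherits(w, "synergy_set")) w$W else as.matrix(w)))
  }
  pool <- as.matrix(pool)
  if (length(pool) == 0L || ncol(pool) == 0L) {
    stop_emg("empty synergy pool", class = "emg_pool")
  }
  if (n_random < 2) stop_emg("n_random must be >= 2", class = "emg_invalid")
  pct <- if (n_comparisons > 1) 100 * (1 - alpha / n_comparisons) else percentile
  X <- with_seed(seed, {
    if (position_preserving) {
      t(vapply(seq_len(nrow(pool)), function(m) {
        sample(pool[m, ], n_random, replace = TRUE)
      }, numeric(n_random)))
    } else {
      matrix(sample(as.numeric(pool), nrow(pool) * n_random, replace = TRUE),
             nrow(pool), n_random)
    }
  })
  X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  R <- crossprod(X)
  r <- sort(R[upper.tri(R)])
  n_pairs <- length(r)
  thr <- r[ceiling(pct / 100 * n_pairs)]
  structure(
    list(threshold = thr, n_pairs = n_pairs, percentile_used = pct,
         null_params = list(n_random = n_random, percentile = percentile,
                            alpha = alpha, n_comparisons = n_comparisons,
                            seed = as.integer(seed),
                            position_preserving = position_preserving,
                            pool_size = ncol(pool))),
    class = "perm_threshold"
  )
}

#' Mark matched pairs as significant against a similarity threshold
#'
#' @param match A [match_synergies()] result.
#' @param threshold A [permutation_threshold()] result or a bare number.
#' @return The `match_result` with `threshold`, `significant` and
#'   `null_params` filled in.
#' @export
apply_threshold <- function(match, threshold) {
  stopifnot(inherits(match, "match_result"))
  if (inherits(threshold, "perm_threshold")) {
    match$null_params <- threshold$null_params
    threshold <- threshold$threshold
  }
  match$threshold <- threshold
  match$significant <- match$pairs$similarity > threshold
  match
}

#' Optimized activations for a fixed synergy basis
#'
#' Solves, per pooled-matrix column, the nonnegative least-squares problem
#' `min ||e - W c||^2, c >= 0` (Lawson-Hanson), giving the optimized
#' activation profiles C' for reconstructing one condition's EMG with
#' another condition's synergies.
#'
#' @param W A `synergy_set` (or matrix) with unit-norm columns.
#' @param E Nonnegative matrix or `pooled_emg`.
#' @return An `activation_set` carrying E's column labels.
#' @export
nnls_activations <- function(W, E) {
  pooled <- if (inherits(E, "pooled_emg")) E else NULL
  Wm <- if (inherits(W, "synergy_set")) W$W else as.matrix(W)
  Em <- as_pooled_matrix(E)
  if (nrow(Wm) != nrow(Em)) {
    stop_emg("W has %d muscles but E has %d rows", nrow(Wm), nrow(Em),
             class = "emg_shape")
  }
  C <- vapply(seq_len(ncol(Em)), function(j) {
    pracma::lsqnonneg(Wm, Em[, j])$x
  }, numeric(ncol(Wm)))
  C <- matrix(C, nrow = ncol(Wm))
  activation_set(C, trial_index = pooled$trial_index,
                 direction_deg = pooled$direction_deg)
}

#' Cross-validated EMG reconstruction across conditions
#'
#' Reconstructs condition B's pooled EMG with condition A's synergies via
#' nonnegative least squares and reports the reconstructed global VAF next
#' to B's own (same-condition) global VAF. The comparison is directional:
#' A reconstructing B need not equal B reconstructing A.
#'
#' @param Wa `synergy_set` of condition A.
#' @param Eb `pooled_emg` (or matrix) of condition B.
#' @param gvaf_original_b Condition B's own global VAF (percent), e.g. from
#'   its [nnmf()] fit at the selected order.
#' @return A `crossval_result` list: `gvaf_original`, `gvaf_reconstructed`,
#'   `gvaf_drop`.
#' @export
cross_validate <- function(Wa, Eb, gvaf_original_b) {
  Cb <- nnls_activations(Wa, Eb)
  v <- vaf(Eb, if (inherits(Wa, "synergy_set")) Wa$W else Wa, Cb$C)
  structure(
    list(gvaf_original = gvaf_original_b, gvaf_reconstructed = v$gvaf,
         gvaf_drop = gvaf_original_b - v$gvaf),
    class = "crossval_result"
  )
}

#' Two one-sided tests (TOST) for gVAF equivalence
#'
#' Paired equivalence test of two per-participant gVAF vectors: two
#' one-sided paired t-tests of the mean difference against -margin and
#' +margin. Equivalence is declared when both one-sided tests reject at
#' `alpha`, i.e. the mean difference is demonstrably inside the margin.
#' When the paired differences have zero variance the t statistics are
#' undefined and the decision falls back to the exact difference:
#' equivalent iff `|mean difference| < margin`.
#'
#' @param x,y Paired numeric vectors (e.g. original and reconstructed gVAF
#'   per participant), equal length >= 2.
#' @param margin Equivalence margin in gVAF percentage points (default 5).
#' @param alpha One-sided level (default 0.05).
#' @return A `tost_result` list: `p_lower`, `p_upper`, `equivalent`,
#'   `mean_diff`, `margin`, `alpha`, `n`.
#' @export
tost_equivalence <- function(x, y, margin = 5, alpha = 0.05) {
  if (length(x) != length(y)) stop_emg("x and y must be paired", class = "emg_pairing")
  if (length(x) < 2) stop_emg("need at least 2 pairs", class = "emg_pairing")
  if (margin <= 0) stop_emg("margin must be > 0", class = "emg_invalid")
  d <- x - y
  md <- mean(d)
  sdd <- stats::sd(d)
  n <- length(d)
  if (sdd == 0) {
    eq <- abs(md) < margin
    p <- if (eq) 0 else 1
    res <- list(p_lower = p, p_upper = p, equivalent = eq)
  } else {
    se <- sdd / sqrt(n)
    t_lower <- (md + margin) / se # H0: mean diff <= -margin
    t_upper <- (md - margin) / se # H0: mean diff >= +margin
    p_lower <- stats::pt(t_lower, df = n - 1, lower.tail = FALSE)
    p_upper <- stats::pt(t_upper, df = n - 1, lower.tail = TRUE)
    res <- list(p_lower = p_lower, p_upper = p_upper,
                equivalent = p_lower < alpha && p_upper < alpha)
  }
  structure(c(res, list(mean_diff = md, margin = margin, alpha = alpha, n = n)),
            class = "tost_result")
}
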