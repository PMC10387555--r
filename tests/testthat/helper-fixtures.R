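# small, fast fixtures shared across test files

# a light reaching dataset: short trials, reduced rates, few reps
small_reaching_dataset <- function(seed = 1, n_reps = 1, snr = 10,
                                   n_synergies = 3) {
  gt <- make_ground_truth(13, n_synergies, seed = seed, snr = snr)
  list(gt = gt,
       ds = synthesize_dataset(gt, "reaching", "Distal", n_reps = n_reps,
                               seed = seed, fs_emg = 500, fs_aux = 500))
}

# an exactly factorizable nonnegative matrix of given nonnegative rank
exact_rank_matrix <- function(n_row = 4, n_col = 6, k = 2, seed = 42) {
  with_seed_local(seed, {
    W0 <- matrix(stats::runif(n_row * k), n_row, k)
    C0 <- matrix(stats::runif(k * n_col), k, n_col)
    list(E = W0 %*% C0, W0 = W0, C0 = C0)
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# brute-force change-point oracle: explicit loop over all splits using var()
brute_force_changepoint <- function(x) {
  x <- sort(x)
  n <- length(x)
  best <- Inf; best_j <- NA
  for (j in 1:(n - 1)) {
    left <- x[1:j]; right <- x[(j + 1):n]
    cost <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
    if (cost < best) { best <- cost; best_j <- j }
  }
  list(change_index = best_j, t = x[best_j + 1])
}

# normalized-space synergies mapped back to generative units for comparison
recovered_vs_truth <- function(fit, pooled, gt) {
  Wd <- denormalize_synergies(fit$W, pooled)
  match_synergies(Wd, gt$W_true)
}
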