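# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed
#'
#' Counter-based splitting rule used throughout the package (per-trial
#' seeds, per-restart seeds): child `i` gets
#' `(seed + 104729 * i) mod (2^31 - 1)`. 104729 is prime, so distinct
#' counters map to distinct seeds for any realistic number of units.
#'
#' @param seed Master integer seed.
#' @param counter Unit index (trial number, restart number, ...).
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(counter)) %% 2147483647)
}

# wrap angles in degrees to [0, 360)
wrap_deg <- function(x) {
  y <- x %% 360
  y[y == 360] <- 0
  y
}

# smallest absolute circular difference in degrees, in [0, 180]
circ_diff_deg <- function(a, b) {
  d <- abs(wrap_deg(a) - wrap_deg(b)) %% 360
  pmin(d, 360 - d)
}

# polynomial rolling hash of a character string, returned as 8 hex digits;
# used to stamp result records with the configuration they came from
config_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 4294967291
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

stop_emg <- function(fmt, ..., class) {
  stop(structure(
    class = c(class, "emgsynergy_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
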