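`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so surrounding code is unaffected.
#' Used internally to give the simulator independent streams for spike
#' sampling, jitter, amplitude variability and noise.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation; keeps every derived seed a valid 32-bit
# integer so independent streams can be spawned from one user seed.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 1e6) * 1013 + 9973 * k) %% 2147483629L
}

# Cosine similarity between two vectors; 0 (with optional warning) when a
# norm vanishes.
cosine_sim <- function(x, y, warn_zero = FALSE) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    if (warn_zero) warning("zero-norm vector in cosine similarity; returning 0")
    return(0)
  }
  sum(x * y) / (nx * ny)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name))
  invisible(x)
}
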