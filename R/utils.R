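#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, then restores the caller's RNG
#' state, so seeded simulation calls do not perturb the global random stream.
#' With `seed = NULL` the expression runs on the current stream unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_rng_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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

# trapezoidal quadrature on an ordered grid
trapz <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2)
  sum(diff(x) * (y[-n] + y[-1]) / 2)
}

# trapezoid weights w such that sum(w * y) == trapz(x, y)
trapz_weights <- function(x) {
  n <- length(x)
  d <- diff(x)
  c(d[1] / 2, (d[-(n - 1)] + d[-1]) / 2, d[n - 1] / 2)
}

# child seeds derived deterministically from a master seed; values stay in
# [1, 2^31 - 2] so they are valid set.seed() inputs on any platform
derive_seeds <- function(master_seed, n) {
  with_rng_seed(master_seed, sample.int(.Machine$integer.max - 1L, n,
                                        replace = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)
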