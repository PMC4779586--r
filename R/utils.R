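`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Rounding used at the reporting layer for percentages: halves round up
#' (away from zero), unlike [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return `x` rounded to `digits` digits with ties away from zero.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5))
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run code with a private RNG stream seeded by `seed`, restoring the caller's
# .Random.seed afterwards so library calls never perturb user-level RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

check_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer", name), call. = FALSE)
  }
  if (x < min) stop(sprintf("`%s` must be >= %d", name, min), call. = FALSE)
  as.integer(x)
}

check_numeric_vector <- function(x, name, finite = TRUE) {
  if (is.matrix(x) && any(dim(x) == 1L)) x <- drop(x)
  if (!is.numeric(x) || length(x) < 1L) {
    stop(sprintf("`%s` must be a numeric vector", name), call. = FALSE)
  }
  if (finite && !all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  as.numeric(x)
}
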