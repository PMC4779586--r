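#' Reconstruction-quality criteria
#'
#' Standard criteria for judging a compressed-sensing pipeline on a frame of
#' acceleration data:
#'
#' * Compression ratio, `compression_ratio()`: the fraction of samples
#'   removed, \eqn{CR = (N - M)/N \times 100\%}. Higher CR means fewer
#'   measurements transmitted and a harder reconstruction problem.
#'   `compression_ratio_literal()` returns the alternative quotient form
#'   \eqn{N/M \times 100\%} for completeness; the subtractive convention is
#'   the package default and is what all sweep utilities use.
#' * Normalized mean square error, `nmse()`:
#'   \eqn{\|X - \hat X\|_2^2 / \|X\|_2^2}.
#' * Signal-to-noise ratio in dB, `snr_db()`:
#'   \eqn{10 \log_{10}(\|X\|^2 / \|X - \hat X\|^2) = -10\log_{10} NMSE};
#'   returns `Inf` for a perfect reconstruction.
#' * Pearson correlation, `pearson_r()`: the sample correlation between the
#'   raw and reconstructed frames.
#'
#' @param N,M frame length and number of measurements, `1 <= M <= N`.
#' @param x,xhat raw and reconstructed signal, equal-length numeric vectors.
#' @return A single number: a percentage for the compression ratios, a
#'   nonnegative real for `nmse()`, decibels (possibly `Inf`) for `snr_db()`,
#'   a value in `[-1, 1]` for `pearson_r()`.
#' @examples
#' compression_ratio(512, 256)          # 50
#' nmse(c(1, 1), c(1, 0))               # 0.5
#' snr_db(c(1, 1), c(1, 0))             # 10*log10(2)
#' @name reconstruction_metrics
NULL

#' @rdname reconstruction_metrics
#' @export
compression_ratio <- function(N, M) {
  N <- check_scalar_count(N, "N"); M <- check_scalar_count(M, "M")
  if (M > N) stop("`M` must not exceed `N`", call. = FALSE)
  (N - M) / N * 100
}

#' @rdname reconstruction_metrics
#' @export
compression_ratio_literal <- function(N, M) {
  N <- check_scalar_count(N, "N"); M <- check_scalar_count(M, "M")
  if (M > N) stop("`M` must not exceed `N`", call. = FALSE)
  N / M * 100
}

check_pair <- function(x, xhat) {
  x <- check_numeric_vector(x, "x")
  xhat <- check_numeric_vector(xhat, "xhat")
  if (length(x) != length(xhat)) {
    stop("`x` and `xhat` must have equal length", call. = FALSE)
  }
  list(x = x, xhat = xhat)
}

#' @rdname reconstruction_metrics
#' @export
nmse <- function(x, xhat) {
  p <- check_pair(x, xhat)
  denom <- sum(p$x^2)
  if (denom == 0) stop("NMSE is undefined for an all-zero reference signal",
                       call. = FALSE)
  sum((p$x - p$xhat)^2) / denom
}

#' @rdname reconstruction_metrics
#' @export
snr_db <- function(x, xhat) {
  e <- nmse(x, xhat)
  if (e == 0) Inf else -10 * log10(e)
}

#' @rdname reconstruction_metrics
#' @export
pearson_r <- function(x, xhat) {
  p <- check_pair(x, xhat)
  if (length(p$x) < 2L) stop("Pearson correlation needs length >= 2",
                             call. = FALSE)
  if (var(p$x) == 0 || var(p$xhat) == 0) {
    stop("Pearson correlation is undefined for a zero-variance input",
         call. = FALSE)
  }
  cor(p$x, p$xhat)
}

#' Bundle all reconstruction criteria for one frame
#'
#' @param x,xhat raw and reconstructed frames.
#' @param M number of measurements used (for the compression ratio);
#'   defaults to `length(x)` (no compression).
#' @param algorithm optional algorithm label carried into the report.
#' @return A `reconstruction_report` list with fields `algorithm`, `N`, `M`,
#'   `cr`, `nmse`, `snr_db`, `pearson_r`.
#' @examples
#' x <- sin(seq(0, 2 * pi, length.out = 64))
#' reconstruction_report(x, x + rnorm(64, sd = 0.01), M = 32)
#' @export
reconstruction_report <- function(x, xhat, M = length(x), algorithm = NA_character_) {
  p <- check_pair(x, xhat)
  N <- length(p$x)
  structure(list(
    algorithm = algorithm, N = N, M = as.integer(M),
    cr = compression_ratio(N, M),
    nmse = nmse(p$x, p$xhat),
    snr_db = snr_db(p$x, p$xhat),
    pearson_r = pearson_r(p$x, p$xhat)
  ), class = "reconstruction_report")
}

#' @export
print.reconstruction_report <- function(x, ...) {
  cat(sprintf(
    "<reconstruction_report> %s N=%d M=%d CR=%.1f%%  NMSE=%.3g  SNR=%.2f dB  r=%.4f\n",
    x$algorithm, x$N, x$M, x$cr, x$nmse, x$snr_db, x$pearson_r))
  invisible(x)
}

#' @export
as.data.frame.reconstruction_report <- function(x, ...) {
  data.frame(algorithm = x$algorithm, N = x$N, M = x$M, cr = x$cr,
             nmse = x$nmse, snr_db = x$snr_db, pearson_r = x$pearson_r,
             stringsAsFactors = FALSE)
}
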