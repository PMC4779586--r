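#' Block partition of a signal frame
#'
#' BSBL models a length-N frame as a concatenation of `l` contiguous blocks
#' of sizes `h_1, ..., h_l` (summing to N). The partition is a user choice,
#' not a property of the data; equal blocks of 20 samples are the default
#' used throughout the reconstruction experiments.
#'
#' @param N frame length.
#' @param block_size block length for an equal partition (the final block is
#'   shorter when `N` is not divisible).
#' @param sizes explicit block sizes overriding `block_size`; must be positive
#'   and sum to `N`.
#' @return A `block_partition` object: list with `sizes`, `l` (block count),
#'   `N`, and `index`, a list of the sample indices of each block.
#' @examples
#' block_partition(500, 20)   # 25 blocks of 20
#' block_partition(10, sizes = c(4, 3, 3))
#' @export
block_partition <- function(N, block_size = 20, sizes = NULL) {
  N <- check_scalar_count(N, "N")
  if (is.null(sizes)) {
    block_size <- check_scalar_count(block_size, "block_size")
    if (block_size > N) block_size <- N
    l <- ceiling(N / block_size)
    sizes <- rep(block_size, l)
    sizes[l] <- N - block_size * (l - 1L)
  } else {
    sizes <- vapply(sizes, check_scalar_count, integer(1), name = "sizes")
    if (sum(sizes) != N) stop("block sizes must sum to N", call. = FALSE)
  }
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  index <- Map(function(s, e) s:e, starts, ends)
  structure(list(sizes = as.integer(sizes), l = length(sizes), N = N,
                 index = index),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat(sprintf("<block_partition> N=%d, l=%d blocks, sizes: %s\n", x$N, x$l,
              if (length(unique(x$sizes)) == 1L)
                sprintf("all %d", x$sizes[1])
              else paste(x$sizes, collapse = ", ")))
  invisible(x)
}

as_partition <- function(partition, N) {
  if (is.null(partition)) return(block_partition(N))
  if (inherits(partition, "block_partition")) {
    if (partition$N != N) stop("partition is for a different frame length",
                               call. = FALSE)
    return(partition)
  }
  block_partition(N, sizes = partition)
}

#' Sparsifying bases
#'
#' An orthonormal N x N transform \eqn{\Psi} in which signals are assumed
#' compressible, `X = Psi %*% alpha`. `dct_basis()` builds the orthonormal
#' DCT-II basis (columns are cosine atoms); `identity_basis()` the trivial
#' time-domain basis.
#'
#' @param N transform size.
#' @return A `sparsifying_basis` object with fields `matrix` (N x N,
#'   orthonormal) and `kind` (`"dct"` or `"identity"`).
#' @examples
#' Psi <- dct_basis(8)
#' max(abs(crossprod(as.matrix(Psi)) - diag(8))) < 1e-12
#' @export
dct_basis <- function(N) {
  N <- check_scalar_count(N, "N")
  n <- seq_len(N) - 0.5           # sample positions 0.5, 1.5, ...
  k <- seq_len(N) - 1             # frequency index 0, ..., N-1
  C <- sqrt(2 / N) * cos(pi * outer(k, n) / N)
  C[1, ] <- C[1, ] / sqrt(2)
  structure(list(matrix = t(C), kind = "dct"), class = "sparsifying_basis")
}

#' @rdname dct_basis
#' @export
identity_basis <- function(N) {
  N <- check_scalar_count(N, "N")
  structure(list(matrix = diag(N), kind = "identity"),
            class = "sparsifying_basis")
}

#' @export
as.matrix.sparsifying_basis <- function(x, ...) x$matrix

#' @export
print.sparsifying_basis <- function(x, ...) {
  cat(sprintf("<sparsifying_basis> %s, %d x %d\n", x$kind,
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

as_basis_matrix <- function(basis, tol = 1e-8) {
  Psi <- if (inherits(basis, "sparsifying_basis")) basis$matrix
         else if (is.matrix(basis) && is.numeric(basis)) basis
         else stop("`basis` must be a sparsifying_basis or numeric matrix",
                   call. = FALSE)
  if (nrow(Psi) != ncol(Psi) ||
      max(abs(crossprod(Psi) - diag(ncol(Psi)))) > tol) {
    stop("sparsifying basis must be orthonormal (t(Psi) %*% Psi = I)",
         call. = FALSE)
  }
  Psi
}
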