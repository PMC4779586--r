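#' Measurement matrices for compressed sensing of acceleration data
#'
#' A `sensing_matrix` is the M x N linear operator \eqn{\Phi} applied on the
#' body-worn device to compress a length-N acceleration frame into M
#' measurements, \eqn{Y = \Phi X}. Three kinds are supported:
#'
#' * `sparse_binary`: every column holds exactly `d` ones at uniformly drawn
#'   row positions and zeros elsewhere. This is the low-energy design: a
#'   matrix-vector product costs only `d` additions per sample and the matrix
#'   is regenerable on both ends of the link from `(M, N, d, seed)`.
#' * `gaussian`: i.i.d. N(0, 1/M) entries, so columns have unit expected
#'   squared norm.
#' * `bernoulli`: i.i.d. entries \eqn{\pm 1/\sqrt{M}} with equal probability.
#'
#' Generation is deterministic given the seed; regenerating with identical
#' arguments yields a bitwise-identical matrix. For sparse binary matrices a
#' draw with an all-zero row (a wasted measurement) is rejected and redrawn,
#' up to 100 attempts.
#'
#' @param M number of measurements (rows), `M <= N`.
#' @param N frame length (columns).
#' @param d column weight: number of ones per column, `1 <= d <= M`
#'   (sparse binary only).
#' @param seed integer seed making the construction reproducible.
#' @param normalize if `TRUE`, scale sparse binary entries by `1/sqrt(d)` so
#'   columns have unit norm; the default keeps literal 0/1 entries.
#' @param kind `"gaussian"` or `"bernoulli"` for [make_dense_random()].
#' @return An object of class `sensing_matrix` with fields `entries` (dense
#'   M x N matrix), `kind`, `M`, `N`, `d` (sparse binary only), `seed`,
#'   `normalized`, and for sparse binary matrices `cols`, a list of the row
#'   indices of the ones in each column.
#' @examples
#' Phi <- make_sparse_binary(M = 4, N = 8, d = 2, seed = 1)
#' colSums(as.matrix(Phi))  # all equal to d
#' @name sensing_matrix
NULL

new_sensing_matrix <- function(entries, kind, M, N, d = NA_integer_,
                               seed = NA_integer_, normalized = FALSE,
                               cols = NULL) {
  structure(
    list(entries = entries, kind = kind, M = M, N = N, d = d, seed = seed,
         normalized = normalized, cols = cols),
    class = "sensing_matrix"
  )
}

#' @rdname sensing_matrix
#' @export
make_sparse_binary <- function(M, N, d, seed = 0L, normalize = FALSE) {
  M <- check_scalar_count(M, "M"); N <- check_scalar_count(N, "N")
  d <- check_scalar_count(d, "d");
  if (d > M) stop("column weight `d` must not exceed the number of rows `M`",
                  call. = FALSE)
  if (M > N) stop("`M` must not exceed `N` (compression requires M <= N)",
                  call. = FALSE)
  cols <- with_seed(seed, {
    res <- NULL
    for (attempt in seq_len(100L)) {
      cand <- lapply(seq_len(N), function(j) sort(sample.int(M, d)))
      rows_hit <- tabulate(unlist(cand), nbins = M)
      if (all(rows_hit > 0L)) { res <- cand; break }
    }
    if (is.null(res)) {
      stop("failed to draw a sparse binary matrix without an all-zero row ",
           "in 100 attempts; increase d or M", call. = FALSE)
    }
    res
  })
  entries <- matrix(0, M, N)
  for (j in seq_len(N)) entries[cols[[j]], j] <- 1
  if (normalize) entries <- entries / sqrt(d)
  new_sensing_matrix(entries, "sparse_binary", M, N, d = d, seed = as.integer(seed),
                     normalized = normalize, cols = cols)
}

#' @rdname sensing_matrix
#' @export
make_dense_random <- function(M, N, kind = c("gaussian", "bernoulli"),
                              seed = 0L) {
  M <- check_scalar_count(M, "M"); N <- check_scalar_count(N, "N")
  if (M > N) stop("`M` must not exceed `N`", call. = FALSE)
  kind <- match.arg(kind)
  entries <- with_seed(seed, {
    if (kind == "gaussian") {
      matrix(rnorm(M * N), M, N) / sqrt(M)
    } else {
      matrix(sample(c(-1, 1), M * N, replace = TRUE), M, N) / sqrt(M)
    }
  })
  new_sensing_matrix(entries, kind, M, N, seed = as.integer(seed))
}

#' @export
as.matrix.sensing_matrix <- function(x, ...) x$entries

#' @export
dim.sensing_matrix <- function(x) c(x$M, x$N)

#' @export
print.sensing_matrix <- function(x, ...) {
  cat(sprintf("<sensing_matrix> %s, %d x %d", x$kind, x$M, x$N))
  if (x$kind == "sparse_binary") {
    cat(sprintf(", column weight d = %d%s", x$d,
                if (x$normalized) " (1/sqrt(d) scaled)" else ""))
  }
  cat(sprintf(", seed = %s\n", x$seed))
  invisible(x)
}

as_phi_matrix <- function(Phi) {
  if (inherits(Phi, "sensing_matrix")) Phi$entries
  else if (is.matrix(Phi) && is.numeric(Phi)) Phi
  else stop("`Phi` must be a sensing_matrix or a numeric matrix", call. = FALSE)
}

#' Compress a signal frame
#'
#' Applies the measurement operator: `Y = Phi %*% X`, reducing a length-N
#' frame to M linear measurements.
#'
#' @param Phi a [sensing_matrix] (or plain numeric matrix).
#' @param x numeric vector of length `N`.
#' @return Numeric vector of length `M`.
#' @examples
#' Phi <- make_sparse_binary(4, 8, 2, seed = 1)
#' y <- compress(Phi, rnorm(8))
#' @export
compress <- function(Phi, x) {
  A <- as_phi_matrix(Phi)
  x <- check_numeric_vector(x, "x")
  if (length(x) != ncol(A)) {
    stop(sprintf("signal length %d does not match matrix width N = %d",
                 length(x), ncol(A)), call. = FALSE)
  }
  drop(A %*% x)
}

#' Serialize and regenerate measurement matrices
#'
#' A matrix descriptor is the small JSON-serializable record
#' `{kind, M, N, d, seed, normalized}` from which the exact matrix can be
#' regenerated bit-for-bit on the receiving end, so only the descriptor (not
#' the matrix) needs to travel with the compressed data.
#'
#' @param Phi a [sensing_matrix].
#' @param desc a descriptor list, or a path to a JSON descriptor file.
#' @param path file path for reading/writing.
#' @return `matrix_descriptor()` returns a named list; `matrix_from_descriptor()`
#'   the regenerated [sensing_matrix]; `write_matrix_json()`/`write_matrix_csv()`
#'   return `path` invisibly; `read_matrix_csv()` a plain numeric matrix.
#' @examples
#' Phi <- make_sparse_binary(4, 8, 2, seed = 7)
#' Phi2 <- matrix_from_descriptor(matrix_descriptor(Phi))
#' identical(as.matrix(Phi), as.matrix(Phi2))
#' @export
matrix_descriptor <- function(Phi) {
  stopifnot(inherits(Phi, "sensing_matrix"))
  list(kind = Phi$kind, M = Phi$M, N = Phi$N,
       d = if (is.na(Phi$d)) NULL else Phi$d,
       seed = Phi$seed, normalized = isTRUE(Phi$normalized))
}

#' @rdname matrix_descriptor
#' @export
matrix_from_descriptor <- function(desc) {
  if (is.character(desc) && length(desc) == 1L) {
    desc <- jsonlite::read_json(desc, simplifyVector = TRUE)
  }
  kind <- desc$kind %||% stop("descriptor lacks `kind`", call. = FALSE)
  if (kind == "sparse_binary") {
    make_sparse_binary(desc$M, desc$N, desc$d, seed = desc$seed,
                       normalize = isTRUE(desc$normalized))
  } else {
    make_dense_random(desc$M, desc$N, kind, seed = desc$seed)
  }
}

#' @rdname matrix_descriptor
#' @export
write_matrix_json <- function(Phi, path) {
  jsonlite::write_json(matrix_descriptor(Phi), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname matrix_descriptor
#' @export
write_matrix_csv <- function(Phi, path) {
  write.table(as_phi_matrix(Phi), path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname matrix_descriptor
#' @export
read_matrix_csv <- function(path) {
  as.matrix(read.csv(path, header = FALSE))
}
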