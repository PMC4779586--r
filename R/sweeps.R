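#' Single-axis test frame of gait-like acceleration
#'
#' Convenience generator used by the sweep protocols: simulates a tri-axial
#' gait-like recording ([gen_gait_signal()]) and returns the first `N`
#' samples of the vertical axis (the axis carrying most gait dynamics),
#' including its gravity offset.
#'
#' @param N frame length in samples.
#' @param class gait class preset (see [gait_presets()]).
#' @param seed RNG seed.
#' @param sample_rate sampling rate in Hz.
#' @return Numeric vector of length `N`.
#' @export
gait_test_frame <- function(N = 512, class = "walk_forward", seed = 0L,
                            sample_rate = 100) {
  N <- check_scalar_count(N, "N")
  sig <- gen_gait_signal(duration = (N + sample_rate) / sample_rate,
                         sample_rate = sample_rate, class = class, seed = seed)
  sig[3, seq_len(N)]
}

cr_to_M <- function(N, cr) {
  M <- as.integer(round(N * (1 - cr / 100)))
  if (M < 1L || M > N) stop(sprintf("compression ratio %g%% is out of range",
                                    cr), call. = FALSE)
  M
}

#' Column-weight sweep for the sparse binary matrix
#'
#' Measures reconstruction error as a function of the column weight `d` at
#' several compression ratios: for each (d, CR) cell it compresses `trials`
#' synthetic gait frames with fresh sparse binary matrices and reconstructs
#' them, reporting the median NMSE. Cells with `d > M` are skipped.
#'
#' @param d_values column weights to try.
#' @param cr_values compression ratios in percent (the `(N - M)/N`
#'   convention).
#' @param N frame length.
#' @param trials frames per cell.
#' @param algo,basis,block_size reconstruction pipeline settings (defaults:
#'   BSBL-BO in the DCT basis with blocks of 20 coefficients).
#' @param class gait class of the synthetic frames.
#' @param seed base RNG seed.
#' @return Data frame with columns `d`, `cr`, `M`, `median_nmse`, `trials`.
#' @export
sweep_column_weight <- function(d_values = c(2, 4, 6, 8, 12, 16),
                                cr_values = c(30, 50, 80), N = 512,
                                trials = 5, algo = "bsbl-bo", basis = "dct",
                                block_size = 20, class = "walk_forward",
                                seed = 0L) {
  Psi <- make_basis(basis, N)
  rows <- list()
  for (cr in cr_values) {
    M <- cr_to_M(N, cr)
    for (d in d_values) {
      if (d > M) next
      errs <- vapply(seq_len(trials), function(i) {
        s <- seed * 1000L + i
        x <- gait_test_frame(N, class, seed = s)
        Phi <- make_sparse_binary(M, N, d, seed = s + 500L)
        xhat <- reconstruct_signal(compress(Phi, x), Phi, algo, basis = Psi,
                                   partition = block_partition(N, block_size),
                                   opts = default_algo_opts(algo))
        nmse(x, xhat)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        d = d, cr = cr, M = M, median_nmse = median(errs), trials = trials)
    }
  }
  do.call(rbind, rows)
}

#' Compression-ratio sweep across measurement-matrix kinds
#'
#' Reconstruction error versus compression ratio for the sparse binary,
#' Gaussian, and Bernoulli measurement matrices, on synthetic gait frames.
#'
#' @inheritParams sweep_column_weight
#' @param kinds matrix kinds to compare.
#' @param d column weight of the sparse binary matrix.
#' @return Data frame with columns `kind`, `cr`, `M`, `median_nmse`,
#'   `trials`.
#' @export
sweep_compression <- function(cr_values = c(30, 40, 50, 60, 70, 80),
                              kinds = c("sparse_binary", "gaussian",
                                        "bernoulli"),
                              N = 512, d = 8, trials = 5, algo = "bsbl-bo",
                              basis = "dct", block_size = 20,
                              class = "walk_forward", seed = 0L) {
  Psi <- make_basis(basis, N)
  rows <- list()
  for (kind in kinds) {
    for (cr in cr_values) {
      M <- cr_to_M(N, cr)
      errs <- vapply(seq_len(trials), function(i) {
        s <- seed * 1000L + i
        x <- gait_test_frame(N, class, seed = s)
        Phi <- if (kind == "sparse_binary") {
          make_sparse_binary(M, N, min(d, M), seed = s + 500L)
        } else {
          make_dense_random(M, N, kind, seed = s + 500L)
        }
        xhat <- reconstruct_signal(compress(Phi, x), Phi, algo, basis = Psi,
                                   partition = block_partition(N, block_size),
                                   opts = default_algo_opts(algo))
        nmse(x, xhat)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, cr = cr, M = M, median_nmse = median(errs),
        trials = trials)
    }
  }
  do.call(rbind, rows)
}

#' Reconstruction-algorithm comparison on gait frames
#'
#' The reconstruction-comparison protocol: for each trial a synthetic gait
#' frame is compressed with a sparse binary matrix (column weight `d`) and
#' reconstructed by every requested algorithm in the DCT basis; NMSE, SNR
#' and Pearson correlation are recorded per trial and algorithm.
#'
#' @inheritParams sweep_column_weight
#' @param M number of measurements.
#' @param algos registered reconstructor names (see
#'   [list_reconstructors()]).
#' @param d sparse binary column weight.
#' @param basis sparsifying basis for all algorithms (default DCT).
#' @param block_size BSBL block size on the coefficient vector.
#' @param opts named list of per-algorithm option lists.
#' @return Data frame with one row per (trial, algorithm): `trial`,
#'   `algorithm`, `N`, `M`, `cr`, `nmse`, `snr_db`, `pearson_r`.
#' @export
compare_reconstructors <- function(N = 512, M = 256,
                                   algos = c("bsbl-bo", "omp", "sp", "sl0",
                                             "bp"),
                                   trials = 20, d = 8, basis = "dct",
                                   block_size = 20, class = "walk_forward",
                                   seed = 0L, opts = list()) {
  Psi <- make_basis(basis, N)
  part <- block_partition(N, block_size)
  rows <- list()
  for (i in seq_len(trials)) {
    s <- seed * 1000L + i
    x <- gait_test_frame(N, class, seed = s)
    Phi <- make_sparse_binary(M, N, min(d, M), seed = s + 500L)
    y <- compress(Phi, x)
    for (algo in algos) {
      xhat <- reconstruct_signal(y, Phi, algo, basis = Psi, partition = part,
                                 opts = opts[[algo]] %||% default_algo_opts(algo))
      rep <- reconstruction_report(x, xhat, M = M, algorithm = algo)
      rows[[length(rows) + 1L]] <- cbind(data.frame(trial = i),
                                         as.data.frame(rep))
    }
  }
  do.call(rbind, rows)
}

# Protocol defaults for reconstruction from exact (noise-free) measurements:
# the greedy/l1 baselines all solve equality-constrained problems, so BSBL
# runs with the matching noiseless measurement model; BP's iteration cap is
# set past its quality plateau on frames of this size.
default_algo_opts <- function(algo) {
  switch(tolower(algo),
         "bsbl-bo" = list(noiseless = TRUE),
         "bp" = list(max_iter = 5000),
         list())
}

make_basis <- function(basis, N) {
  if (inherits(basis, "sparsifying_basis") || is.matrix(basis)) return(basis)
  switch(match.arg(basis, c("dct", "identity")),
         dct = dct_basis(N), identity = identity_basis(N))
}
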