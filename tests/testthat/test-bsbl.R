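test_that("posterior moments reduce to known algebraic limits", {
  # orthonormal rows, unit prior, vanishing noise: mu -> t(Phi) y
  Q <- qr.Q(qr(matrix(rand_signal(36, 1), 6, 6)))[, 1:3]
  Phi <- t(Q)                               # 3 x 6, Phi %*% t(Phi) = I
  y <- c(1, -2, 0.5)
  pm <- posterior_moments(Phi, y, diag(6), rho = 1e-12)
  expect_equal(pm$mu, drop(t(Phi) %*% y), tolerance = 1e-9)
  # zero prior covariance: mu = 0
  pm0 <- posterior_moments(Phi, y, matrix(0, 6, 6), rho = 0.5)
  expect_equal(pm0$mu, numeric(6))
  expect_error(posterior_moments(Phi, c(NA, 1, 2), diag(6), 0.1), "finite")
})

test_that("the two algebraically equivalent posterior formulas agree", {
  set.seed(7)
  for (i in 1:5) {
    N <- 12; M <- 6
    A <- matrix(rnorm(M * N), M, N)
    rho <- runif(1, 0.01, 1)
    # random block-diagonal SPD prior
    part <- block_partition(N, 4)
    Sx <- matrix(0, N, N)
    for (ix in part$index) {
      W <- matrix(rnorm(16), 4)
      Sx[ix, ix] <- crossprod(W) + diag(4) * 0.1
    }
    y <- rnorm(M)
    pm <- posterior_moments(A, y, Sx, rho)
    # direct N x N form (valid because Sx is nonsingular here)
    Sigma_direct <- solve(solve(Sx) + crossprod(A) / rho)
    mu_direct <- drop(Sigma_direct %*% crossprod(A, y)) / rho
    expect_equal(pm$mu, mu_direct, tolerance = 1e-8)
    expect_equal(pm$Sigma, Sigma_direct, tolerance = 1e-8)
    # posterior covariance stays symmetric PSD
    expect_equal(pm$Sigma, t(pm$Sigma))
    expect_gte(min(eigen(pm$Sigma, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
})

test_that("intra-block correlation regularization follows the AR(1) rule", {
  B_id <- estimate_intra_block_correlation(list(diag(4), diag(4)))
  expect_equal(B_id[[1]], diag(4))
  B <- toeplitz(c(1, 0.96, 0.5, 0.2))     # diag 1, first subdiagonal 0.96
  out <- estimate_intra_block_correlation(list(B))
  expect_equal(out[[1]], toeplitz(0.96^(0:3)))
  # degenerate ratio above 1 is clipped at 0.99
  Bd <- matrix(1.2, 3, 3); diag(Bd) <- 1
  out_d <- estimate_intra_block_correlation(list(Bd))
  expect_equal(out_d[[1]][2, 1], 0.99)
})

test_that("BSBL-BO handles zero measurements and full pruning gracefully", {
  Phi <- make_dense_random(10, 40, "gaussian", seed = 1)
  fit <- bsbl_bo(numeric(10), Phi, partition = block_partition(40, 10))
  expect_equal(fit$x, numeric(40))
  expect_equal(fit$state$status, "zero_measurements")
})

test_that("BSBL-BO exactly recovers noiseless block-sparse signals", {
  ok <- 0L
  for (i in 1:5) {
    gen <- gen_block_sparse(N = 200, block_size = 20, k_active = 2, r = 0.9,
                            seed = 100 + i)
    Phi <- make_dense_random(100, 200, "gaussian", seed = 200 + i)
    y <- compress(Phi, gen$signal)
    fit <- bsbl_bo(y, Phi, partition = block_partition(200, 20),
                   noiseless = TRUE)
    # independent oracle: least squares on the true support is exact here
    oracle <- restricted_ls(y, as.matrix(Phi), gen$support)
    expect_lt(nmse(gen$signal, oracle), 1e-12)
    if (nmse(gen$signal, fit$x) < 1e-6) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("pruned blocks contribute exactly zero to the estimate", {
  gen <- gen_block_sparse(N = 200, block_size = 20, k_active = 2, r = 0.8,
                          noise_snr_db = 25, seed = 31)
  Phi <- make_dense_random(100, 200, "gaussian", seed = 32)
  fit <- bsbl_bo(compress(Phi, gen$signal), Phi,
                 partition = block_partition(200, 20))
  st <- fit$state
  expect_true(any(st$lambda == 0))
  for (j in which(st$lambda < 1e-3)) {
    expect_equal(fit$x[st$partition$index[[j]]],
                 numeric(st$partition$sizes[j]))
  }
})

test_that("noise variance is learned to the right order of magnitude", {
  ratios <- vapply(1:10, function(i) {
    gen <- gen_block_sparse(N = 250, block_size = 25, k_active = 3, r = 0.9,
                            seed = 400 + i)
    Phi <- make_dense_random(125, 250, "gaussian", seed = 500 + i)
    y_clean <- compress(Phi, gen$signal)
    true_var <- mean(y_clean^2) * 10^(-20 / 10)   # 20 dB measurement SNR
    set.seed(600 + i)
    y <- y_clean + rnorm(125, sd = sqrt(true_var))
    fit <- bsbl_bo(y, Phi, partition = block_partition(250, 25))
    (fit$state$rho * fit$state$scale^2) / true_var
  }, numeric(1))
  expect_lt(median(pmax(ratios, 1 / ratios)), 3)
})

test_that("a single block spanning the frame still yields a finite estimate", {
  x <- rand_signal(60, 8)
  Phi <- make_dense_random(30, 60, "gaussian", seed = 9)
  fit <- bsbl_bo(compress(Phi, x), Phi, partition = block_partition(60, 60))
  expect_true(all(is.finite(fit$x)))
  expect_equal(fit$state$partition$l, 1L)
})

test_that("basis-domain reconstruction matches its contracts", {
  N <- 64
  Phi <- make_dense_random(32, N, "gaussian", seed = 10)
  # identity basis is exactly time-domain bsbl_bo
  gen <- gen_block_sparse(N = N, block_size = 8, k_active = 2, seed = 11)
  y <- compress(Phi, gen$signal)
  f_id <- reconstruct_in_basis(y, Phi, identity_basis(N),
                               partition = block_partition(N, 8),
                               noiseless = TRUE)
  f_td <- bsbl_bo(y, Phi, partition = block_partition(N, 8),
                  noiseless = TRUE)
  expect_equal(f_id$x, f_td$x, tolerance = 1e-12)
  # exactly DCT-sparse signal, one active coefficient block, M = N/2
  Psi <- dct_basis(N)
  alpha <- numeric(N); alpha[9:13] <- c(3, -2, 1.5, -1, 2)  # one block of 8
  x <- drop(as.matrix(Psi) %*% alpha)
  y2 <- compress(Phi, x)
  fit <- reconstruct_in_basis(y2, Phi, Psi,
                              partition = block_partition(N, 8),
                              noiseless = TRUE)
  oracle <- drop(as.matrix(Psi) %*%
                   restricted_ls(y2, as.matrix(Phi) %*% as.matrix(Psi), 9:13))
  expect_lt(nmse(x, oracle), 1e-12)
  expect_lt(nmse(x, fit$x), 1e-6)
  # non-orthonormal basis is rejected
  bad <- matrix(rnorm(N * N), N)
  expect_error(reconstruct_in_basis(y2, Phi, bad), "orthonormal")
})
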