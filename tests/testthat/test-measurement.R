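test_that("sparse binary matrices have exact column weight and no zero rows", {
  set.seed(42)
  for (rep in 1:12) {
    N <- sample(8:60, 1)
    M <- sample(4:floor(2 * N / 3), 1)   # keep expected row occupancy >= 3
    d <- sample(2:min(M, 6), 1)
    Phi <- make_sparse_binary(M, N, d, seed = rep)
    E <- as.matrix(Phi)
    expect_equal(unname(colSums(E)), rep(d, N))
    expect_true(all(E %in% c(0, 1)))
    expect_true(all(rowSums(E) > 0))
  }
  expect_equal(unname(colSums(as.matrix(make_sparse_binary(4, 8, 2, seed = 0)))),
               rep(2, 8))
})

test_that("sparse binary construction validates arguments", {
  expect_error(make_sparse_binary(4, 8, 5), "exceed")
  expect_error(make_sparse_binary(10, 8, 2), "M")
  expect_error(make_sparse_binary(4, 8, 0), ">=")
})

test_that("operating-point matrix (M=256, N=512, d=8) is valid", {
  Phi <- make_sparse_binary(256, 512, 8, seed = 1)
  expect_equal(dim(Phi), c(256L, 512L))
  expect_equal(unname(colSums(as.matrix(Phi))), rep(8, 512))
})

test_that("normalized sparse binary columns have unit norm", {
  Phi <- make_sparse_binary(16, 32, 4, seed = 3, normalize = TRUE)
  expect_equal(unname(sqrt(colSums(as.matrix(Phi)^2))), rep(1, 32))
})

test_that("dense random matrices follow their scaled distributions", {
  B <- make_dense_random(2, 4, "bernoulli", seed = 9)
  expect_true(all(abs(as.matrix(B)) == 1 / sqrt(2)))
  G1 <- make_dense_random(3, 3, "gaussian", seed = 5)
  G2 <- make_dense_random(3, 3, "gaussian", seed = 5)
  expect_identical(as.matrix(G1), as.matrix(G2))
  # column norms concentrate near 1 for tall-and-wide gaussian
  G <- make_dense_random(10, 1000, "gaussian", seed = 7)
  expect_lt(abs(mean(sqrt(colSums(as.matrix(G)^2))) - 1), 0.1)
  expect_error(make_dense_random(2, 4, "cauchy"), "arg")
})

test_that("regeneration from identical arguments is bitwise identical", {
  for (kind in c("gaussian", "bernoulli")) {
    expect_identical(as.matrix(make_dense_random(6, 12, kind, seed = 11)),
                     as.matrix(make_dense_random(6, 12, kind, seed = 11)))
  }
  expect_identical(as.matrix(make_sparse_binary(6, 12, 3, seed = 11)),
                   as.matrix(make_sparse_binary(6, 12, 3, seed = 11)))
})

test_that("compress matches identity, counting, and brute-force oracles", {
  x <- rand_signal(6, 1)
  expect_equal(compress(diag(6), x), x)
  # single 1 per column: y_i counts the ones in row i when x = 1
  Phi1 <- make_sparse_binary(5, 12, 1, seed = 2)
  expect_equal(compress(Phi1, rep(1, 12)),
               unname(rowSums(as.matrix(Phi1))))
  Phi <- make_dense_random(5, 12, "gaussian", seed = 3)
  x <- rand_signal(12, 4)
  expect_equal(compress(Phi, x), naive_multiply(as.matrix(Phi), x),
               tolerance = 1e-12)
  expect_error(compress(Phi, rand_signal(10, 5)), "match")
})

test_that("compression is linear", {
  Phi <- make_sparse_binary(8, 20, 3, seed = 6)
  for (i in 1:5) {
    x1 <- rand_signal(20, i); x2 <- rand_signal(20, i + 50)
    a <- rnorm(1); b <- rnorm(1)
    lhs <- compress(Phi, a * x1 + b * x2)
    rhs <- a * compress(Phi, x1) + b * compress(Phi, x2)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("descriptor and CSV round-trips reproduce the matrix", {
  Phi <- make_sparse_binary(8, 16, 3, seed = 13)
  path_json <- withr::local_tempfile(fileext = ".json")
  write_matrix_json(Phi, path_json)
  expect_identical(as.matrix(matrix_from_descriptor(path_json)),
                   as.matrix(Phi))
  G <- make_dense_random(5, 9, "bernoulli", seed = 4)
  expect_identical(as.matrix(matrix_from_descriptor(matrix_descriptor(G))),
                   as.matrix(G))
  path_csv <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(Phi, path_csv)
  expect_equal(read_matrix_csv(path_csv), as.matrix(Phi),
               ignore_attr = TRUE)
})
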