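# Independent oracles used across the suite; deliberately naive
# implementations that do not share code with the package internals.

# brute-force matrix-vector product
naive_multiply <- function(A, x) {
  out <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) {
    acc <- 0
    for (j in seq_len(ncol(A))) acc <- acc + A[i, j] * x[j]
    out[i] <- acc
  }
  out
}

# least squares restricted to a known support
restricted_ls <- function(y, A, support) {
  alpha <- numeric(ncol(A))
  alpha[support] <- qr.solve(A[, support, drop = FALSE], y)
  alpha
}

# exhaustive search over all k-subsets for the best-fitting support
exhaustive_sparse_fit <- function(y, A, k) {
  combos <- utils::combn(ncol(A), k)
  best <- NULL; best_res <- Inf
  for (c in seq_len(ncol(combos))) {
    s <- combos[, c]
    alpha <- restricted_ls(y, A, s)
    res <- sum((y - A %*% alpha)^2)
    if (res < best_res) { best_res <- res; best <- list(support = s, alpha = alpha) }
  }
  best
}

rand_signal <- function(n, seed) {
  set.seed(seed)
  rnorm(n)
}

# Tropp's exact recovery condition for support S: greedy and l1 methods are
# guaranteed to find S when max_{j not in S} ||pinv(A_S) a_j||_1 < 1.
erc_holds <- function(A, support) {
  As_pinv <- solve(crossprod(A[, support]), t(A[, support]))
  off <- setdiff(seq_len(ncol(A)), support)
  max(colSums(abs(As_pinv %*% A[, off]))) < 1
}
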