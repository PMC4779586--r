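test_that("segmentation enumerates half-open windows with overlap", {
  x <- matrix(rand_signal(3 * 1280, 1), 3)
  wins <- segment(x, 512, 0.5)
  expect_length(wins, 4)
  expect_equal(vapply(wins, `[[`, integer(1), "start"), c(0L, 256L, 512L, 768L))
  expect_equal(wins[[2]]$samples, x[, 257:768])
  # zero overlap: disjoint floor(T/L) windows
  expect_length(segment(x, 512, 0), 2)
  # exactly one window when T equals the window length
  expect_length(segment(x[, 1:512], 512, 0.5), 1)
  expect_warning(w0 <- segment(x[, 1:100], 512, 0.5), "exceeds")
  expect_length(w0, 0)
})

test_that("window features follow the printed moment formulas", {
  # kurtosis of 1..5 under the population-SD convention
  w <- rbind(1:5, c(2, 4, 1, 5, 3), c(5, 1, 4, 2, 3))
  f <- window_features(w)
  expect_length(f, 12)
  expect_equal(unname(f["kurt_x"]), 2.625, tolerance = 1e-12)
  expect_equal(unname(f["sd_x"]), sqrt(2), tolerance = 1e-12)
  # the sample-SD variant gives the conventional adjusted kurtosis
  f2 <- window_features(w, sd_type = "sample")
  expect_equal(unname(f2["kurt_x"]), -1.2, tolerance = 1e-12)
  # data symmetric about its mean has zero skewness
  sym <- rbind(1:5, c(0, 1, 0, -1, 0), c(2, 3, 4, 5, 6))
  fs <- window_features(sym)
  expect_equal(unname(fs[c("skew_x", "skew_y", "skew_z")]), c(0, 0, 0),
               tolerance = 1e-12)
})

test_that("feature extraction validates its inputs", {
  expect_error(window_features(rbind(1:5, rep(2, 5), 1:5)), "axis 'y'")
  expect_error(window_features(matrix(rnorm(9), 3, 3)), "at least 4")
})

test_that("features are invariant to constant axis offsets", {
  w <- matrix(rand_signal(3 * 64, 2), 3)
  f1 <- window_features(w)
  f2 <- window_features(w + c(5, -3, 100))
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("every valid window yields exactly 12 named features", {
  set.seed(5)
  for (i in 1:8) {
    L <- sample(4:600, 1)
    f <- window_features(matrix(rnorm(3 * L), 3))
    expect_length(f, 12)
    expect_true(all(is.finite(f)))
    expect_named(f, c("sd_x", "sd_y", "sd_z", "skew_x", "skew_y", "skew_z",
                      "kurt_x", "kurt_y", "kurt_z", "r_xy", "r_yz", "r_xz"))
  }
})

test_that("binary metrics match the printed formulas", {
  expect_equal(binary_metrics(tp = 19, fn = 1, tn = 19, fp = 1),
               c(accuracy = 95, sensitivity = 95, specificity = 95))
  expect_equal(unname(binary_metrics(tp = 10, fp = 0, tn = 10, fn = 0)),
               c(100, 100, 100))
  m <- binary_metrics(tp = 0, fp = 3, tn = 0, fn = 3)
  expect_equal(unname(m["accuracy"]), 0)
  # undefined sensitivity when no positives exist
  m2 <- binary_metrics(tp = 0, fp = 2, tn = 5, fn = 0)
  expect_true(is.na(m2["sensitivity"]))
  # with equal class sizes, accuracy lies between sensitivity and specificity
  for (i in 1:10) {
    set.seed(i)
    tp <- sample(0:50, 1); fn <- 50 - tp
    tn <- sample(0:50, 1); fp <- 50 - tn
    m <- binary_metrics(tp, fp, tn, fn)
    expect_gte(m[["accuracy"]], min(m[["sensitivity"]], m[["specificity"]]))
    expect_lte(m[["accuracy"]], max(m[["sensitivity"]], m[["specificity"]]))
  }
})

test_that("multiclass metrics handle diagonal, uniform, and degenerate tables", {
  ident <- diag(c(5, 9, 14))
  m <- multiclass_metrics(ident)
  expect_equal(m$overall_accuracy, 100)
  expect_equal(unname(m$recall), rep(100, 3))
  expect_equal(unname(m$precision), rep(100, 3))
  unif <- matrix(3, 4, 4)
  expect_equal(multiclass_metrics(unif)$overall_accuracy, 25)
  # permutation-scaled diagonal: still 100% when predictions are permuted back
  perm <- diag(c(2, 4, 6))[c(2, 3, 1), c(2, 3, 1)]
  expect_equal(multiclass_metrics(perm)$overall_accuracy, 100)
  # empty row gives NA recall for that class
  t0 <- rbind(c(5, 0), c(0, 0))
  expect_true(is.na(multiclass_metrics(t0)$recall[2]))
  expect_error(multiclass_metrics(matrix(1, 2, 3)), "square")
})

test_that("stratified cross-validation balances classes within folds", {
  labels <- rep(c("up", "down"), each = 100)
  cv <- crossval_protocol(labels, folds = 10, seed = 3)
  tab <- table(cv$folds, labels)
  expect_true(all(tab == 10))
  # reproducible by seed
  cv2 <- crossval_protocol(labels, folds = 10, seed = 3)
  expect_identical(cv$folds, cv2$folds)
  # leave-one-out when folds equals the sample count
  cv_loo <- crossval_protocol(rep(c("a", "b"), each = 4), folds = 4, seed = 1)
  expect_equal(sort(unique(cv_loo$folds)), 1:4)
  expect_error(crossval_protocol(c("a", "a", "b"), folds = 2), "fewer")
})

test_that("subject hold-out splits never leak a subject into training", {
  labels <- rep(c("up", "down"), each = 20)
  subjects <- rep(sprintf("s%02d", 1:8), each = 5)
  cv <- crossval_protocol(labels, subjects, folds = 5, seed = 2)
  expect_length(cv$subject_holdout, 8)
  for (s in names(cv$subject_holdout)) {
    sp <- cv$subject_holdout[[s]]
    expect_length(intersect(sp$train, sp$test), 0)
    expect_true(all(subjects[sp$test] == s))
    expect_true(all(subjects[sp$train] != s))
    expect_setequal(c(sp$train, sp$test), seq_along(labels))
  }
})

test_that("feature tables carry window starts and recording metadata", {
  sig <- gen_gait_signal(duration = 16, class = "run", seed = 11)
  ft <- features_from_recording(sig, window_length = 512,
                                overlap_fraction = 0.5)
  expect_equal(nrow(ft), 5)
  expect_equal(ft$window_start, seq(0L, 1024L, by = 256L))
  expect_equal(unique(ft$label), "run")
  expect_error(features_from_recording(sig[, 1:100, drop = FALSE]),
               "shorter")
})

test_that("well-separated synthetic classes are classified accurately", {
  d <- gen_labeled_dataset(c("walk_forward", "run"), windows_per_class = 30,
                           subjects_per_class = 5, seed = 4)
  res <- classify_features(d, classifier = "svm", folds = 5, seed = 9)
  expect_gt(res$cv_metrics$overall_accuracy, 90)
  expect_gt(res$holdout_metrics$overall_accuracy, 90)
  expect_equal(sum(res$cv_confusion), nrow(d))
})
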