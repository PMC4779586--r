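#' Segment a tri-axial recording into overlapping windows
#'
#' Cuts a 3 x T acceleration matrix into full-length windows of
#' `window_length` samples, stepping by
#' `window_length * (1 - overlap_fraction)` (rounded to an integer, at
#' least 1). Windows are half-open sample ranges `[start, start + L)` with
#' 0-based `start`; any trailing samples that cannot fill a complete window
#' are dropped.
#'
#' @param signal numeric 3 x T matrix (rows: ax, ay, az) or T x 3 matrix,
#'   which is transposed automatically.
#' @param window_length window length L in samples (default 512).
#' @param overlap_fraction fraction of overlap between consecutive windows,
#'   in `[0, 1)` (default 0.5).
#' @return A list of `gait_window` objects, each with `samples` (3 x L),
#'   `start` (0-based offset), `length`. Returns an empty list with a
#'   warning when `window_length > T`.
#' @examples
#' x <- matrix(rnorm(3 * 1280), 3)
#' length(segment(x, 512, 0.5))   # 4 windows at 0, 256, 512, 768
#' @export
segment <- function(signal, window_length = 512, overlap_fraction = 0.5) {
  signal <- as_triaxial(signal)
  window_length <- check_scalar_count(window_length, "window_length")
  if (!is.numeric(overlap_fraction) || length(overlap_fraction) != 1L ||
      overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("`overlap_fraction` must be in [0, 1)", call. = FALSE)
  }
  T <- ncol(signal)
  if (window_length > T) {
    warning("window_length exceeds the recording length; no windows produced")
    return(list())
  }
  step <- max(1L, as.integer(round(window_length * (1 - overlap_fraction))))
  starts <- seq.int(0L, T - window_length, by = step)
  lapply(starts, function(s) {
    structure(list(samples = signal[, (s + 1):(s + window_length), drop = FALSE],
                   start = as.integer(s), length = window_length),
              class = "gait_window")
  })
}

as_triaxial <- function(signal) {
  if (inherits(signal, "gait_recording")) signal <- signal$acc
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop("`signal` must be a numeric matrix with 3 axes", call. = FALSE)
  }
  if (nrow(signal) != 3L && ncol(signal) == 3L) signal <- t(signal)
  if (nrow(signal) != 3L) stop("`signal` must be 3 x T (or T x 3)",
                               call. = FALSE)
  signal
}

#' The 12-dimensional windowed gait feature vector
#'
#' For each axis of a tri-axial window, three moment statistics are
#' computed from the mean-centered samples \eqn{d_i = x_i - \bar x}:
#' \deqn{SD = \sqrt{\tfrac{1}{L}\sum d_i^2}}
#' \deqn{Skewness = \frac{L \sum d_i^3}{(L-1)(L-2)\,SD^3}}
#' \deqn{Kurtosis = \frac{L(L+1)}{(L-1)(L-2)(L-3)} \frac{\sum d_i^4}{SD^4}
#'   - \frac{3(L-1)^2}{(L-2)(L-3)}}
#' plus the three inter-axis Pearson correlations (x,y), (y,z), (x,z),
#' giving exactly 12 features per window. The standard deviation inside the
#' higher moments uses the population (1/L) form by default; `sd_type =
#' "sample"` selects the (L-1) denominator, under which the bias-correction
#' prefactors above reduce to the conventional adjusted skewness/kurtosis
#' (e.g. kurtosis of 1..5 becomes -1.2 instead of 2.625).
#'
#' @param w a `gait_window` from [segment()], or a 3 x L numeric matrix.
#' @param sd_type `"population"` (1/L, default) or `"sample"` (1/(L-1)).
#' @return Named numeric vector of length 12: `sd_x, sd_y, sd_z, skew_x,
#'   skew_y, skew_z, kurt_x, kurt_y, kurt_z, r_xy, r_yz, r_xz`.
#' @examples
#' w <- matrix(rnorm(3 * 512), 3)
#' length(window_features(w))   # 12
#' @export
window_features <- function(w, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  x <- if (inherits(w, "gait_window")) w$samples else as_triaxial(w)
  L <- ncol(x)
  if (L < 4L) stop("window length must be at least 4 (kurtosis needs L >= 4)",
                   call. = FALSE)
  axes <- c("x", "y", "z")
  moments <- vapply(1:3, function(a) {
    d <- x[a, ] - mean(x[a, ])
    s2 <- if (sd_type == "population") sum(d^2) / L else sum(d^2) / (L - 1)
    if (s2 == 0) {
      stop(sprintf("axis '%s' has zero variance; features are undefined",
                   axes[a]), call. = FALSE)
    }
    s <- sqrt(s2)
    skew <- L * sum(d^3) / ((L - 1) * (L - 2) * s^3)
    kurt <- (L * (L + 1)) / ((L - 1) * (L - 2) * (L - 3)) * sum(d^4) / s^4 -
      3 * (L - 1)^2 / ((L - 2) * (L - 3))
    c(s, skew, kurt)
  }, numeric(3))
  out <- c(moments[1, ], moments[2, ], moments[3, ],
           cor(x[1, ], x[2, ]), cor(x[2, ], x[3, ]), cor(x[1, ], x[3, ]))
  names(out) <- c(paste0("sd_", axes), paste0("skew_", axes),
                  paste0("kurt_", axes), "r_xy", "r_yz", "r_xz")
  out
}

#' Binary classification metrics
#'
#' Accuracy, sensitivity and specificity (as percentages) from the binary
#' confusion counts:
#' \deqn{Acc = \frac{TP + TN}{TP + FP + TN + FN} \times 100}
#' \deqn{Sen = \frac{TP}{TP + FN} \times 100, \quad
#'       Spe = \frac{TN}{TN + FP} \times 100}
#' A metric whose denominator is zero is returned as `NA`.
#'
#' @param tp,fp,tn,fn nonnegative confusion counts (true/false
#'   positives/negatives).
#' @return Named numeric vector `c(accuracy, sensitivity, specificity)` in
#'   percent.
#' @examples
#' binary_metrics(tp = 19, fn = 1, tn = 19, fp = 1)  # 95 / 95 / 95
#' @export
binary_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("all confusion counts are zero", call. = FALSE)
  pct <- function(num, den) if (den == 0) NA_real_ else num / den * 100
  c(accuracy = pct(tp + tn, sum(counts)),
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp))
}

#' Multiclass confusion-table metrics
#'
#' For a K x K count table whose entry (i, j) is the number of samples of
#' true class i predicted as class j:
#' per-class recall `diag_i / rowsum_i * 100`, per-class precision
#' `diag_j / colsum_j * 100`, and overall accuracy
#' `trace / total * 100`. Classes with an empty row (or column) get `NA`
#' recall (or precision). Values are returned unrounded; apply
#' [round_half_up()] at the reporting layer.
#'
#' @param table K x K numeric matrix of nonnegative counts (K >= 2),
#'   rows = true classes. Dimnames, if present, are carried through.
#' @return List with `overall_accuracy` (percent), `recall` and `precision`
#'   (named per-class percent vectors), and `table`.
#' @examples
#' tab <- diag(c(10, 20, 30))
#' multiclass_metrics(tab)$overall_accuracy   # 100
#' @export
multiclass_metrics <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != ncol(table) || nrow(table) < 2L) {
    stop("`table` must be a square K x K matrix with K >= 2", call. = FALSE)
  }
  if (any(!is.finite(table)) || any(table < 0)) {
    stop("confusion counts must be nonnegative", call. = FALSE)
  }
  total <- sum(table)
  if (total == 0) stop("confusion table is empty", call. = FALSE)
  classes <- rownames(table) %||% paste0("class", seq_len(nrow(table)))
  rs <- rowSums(table); cs <- colSums(table); dg <- diag(table)
  recall <- ifelse(rs > 0, dg / rs * 100, NA_real_)
  precision <- ifelse(cs > 0, dg / cs * 100, NA_real_)
  names(recall) <- names(precision) <- classes
  list(overall_accuracy = sum(dg) / total * 100,
       recall = recall, precision = precision, table = table)
}

#' Cross-validation protocol with subject-level hold-out
#'
#' Builds (a) a class-stratified k-fold assignment of samples, reproducible
#' by seed, and (b) leave-one-subject-out splits for testing generalization
#' across subjects: each subject in turn forms the test set while all other
#' subjects train, so no subject contributes to both sides.
#'
#' @param labels class label per sample (factor or character).
#' @param subjects optional subject identifier per sample; enables the
#'   subject hold-out splits.
#' @param folds number of folds (>= 2).
#' @param seed RNG seed for the stratified assignment.
#' @return List with `folds` (integer fold id per sample, 1..folds) and
#'   `subject_holdout` (named list per subject of `list(train, test)` index
#'   vectors; `NULL` when `subjects` is missing).
#' @examples
#' cv <- crossval_protocol(rep(c("up", "down"), each = 100), folds = 10,
#'                         seed = 1)
#' table(cv$folds, rep(c("up", "down"), each = 100))  # 10 + 10 per fold
#' @export
crossval_protocol <- function(labels, subjects = NULL, folds = 10, seed = 0L) {
  labels <- as.character(labels)
  n <- length(labels)
  folds <- check_scalar_count(folds, "folds", min = 2)
  if (folds > n) stop("more folds than samples", call. = FALSE)
  tab <- table(labels)
  if (any(tab < folds)) {
    stop(sprintf("class '%s' has fewer samples (%d) than folds (%d)",
                 names(tab)[which.min(tab)], min(tab), folds), call. = FALSE)
  }
  assignment <- integer(n)
  with_seed(seed, {
    for (cls in names(tab)) {
      idx <- sample(which(labels == cls))
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  holdout <- NULL
  if (!is.null(subjects)) {
    subjects <- as.character(subjects)
    if (length(subjects) != n) {
      stop("`subjects` must match `labels` in length", call. = FALSE)
    }
    holdout <- lapply(unique(subjects), function(s) {
      list(train = which(subjects != s), test = which(subjects == s))
    })
    names(holdout) <- unique(subjects)
  }
  list(folds = assignment, subject_holdout = holdout)
}

#' Feature table from a recording
#'
#' Segments a tri-axial recording into overlapping windows and extracts the
#' 12-dimensional feature vector of [window_features()] per window, carrying
#' the recording's activity label and subject id into the table.
#'
#' @param rec a `gait_recording` (see [read_csv_recording()]) or 3 x T
#'   numeric matrix.
#' @param window_length,overlap_fraction windowing parameters (see
#'   [segment()]).
#' @return Data frame with the 12 feature columns plus `window_start`,
#'   `label`, `subject`.
#' @export
features_from_recording <- function(rec, window_length = 512,
                                    overlap_fraction = 0.5) {
  wins <- suppressWarnings(segment(rec, window_length, overlap_fraction))
  if (length(wins) == 0L) {
    stop("recording shorter than one window", call. = FALSE)
  }
  out <- do.call(rbind, lapply(wins, function(w) {
    data.frame(as.list(window_features(w)), window_start = w$start)
  }))
  out$label <- if (inherits(rec, "gait_recording")) rec$activity
               else attr(rec, "activity") %||% NA_character_
  out$subject <- if (inherits(rec, "gait_recording")) rec$subject
                 else NA_character_
  out
}

#' Shipped classifier configurations
#'
#' Default hyperparameter settings for the pluggable classifier backends
#' used in the evaluation protocol: a multilayer perceptron (600 training
#' epochs, learning rate 0.3, momentum 0.5), a polynomial-kernel SVM
#' (degree 2, regularization parameter 1), and a KStar-style instance-based
#' learner (global blending 20). Only the MLP (via \pkg{nnet}) and SVM (via
#' \pkg{e1071}) have bundled backends; KStar can be supplied through the
#' plug-in mechanism of [classify_features()].
#'
#' @return Named list of per-classifier configuration lists.
#' @export
classifier_config <- function() {
  list(
    mlp = list(epochs = 600, learning_rate = 0.3, momentum = 0.5, hidden = 6),
    svm = list(kernel = "polynomial", degree = 2, cost = 1, coef0 = 1),
    kstar = list(global_blending = 20)
  )
}

#' Cross-validated classification of windowed gait features
#'
#' Runs the stratified k-fold protocol of [crossval_protocol()] on a feature
#' table, training the chosen backend on each training split and predicting
#' the held-out fold, then (optionally) evaluates leave-one-subject-out
#' generalization. Returns pooled confusion tables and the metrics of
#' [multiclass_metrics()].
#'
#' @param features data frame with the 12 feature columns, a `label` column
#'   and optionally a `subject` column (as produced by
#'   [gen_labeled_dataset()] or [features_from_recording()]).
#' @param classifier `"mlp"`, `"svm"`, or a function
#'   `(train_x, train_y, test_x, config) -> factor of predictions` for a
#'   plug-in backend.
#' @param folds,seed cross-validation protocol parameters.
#' @param config configuration list (defaults from [classifier_config()]).
#' @return List with `cv_confusion`, `cv_metrics`, and (when a `subject`
#'   column is present) `holdout_confusion`, `holdout_metrics`.
#' @export
classify_features <- function(features, classifier = "mlp", folds = 10,
                              seed = 0L, config = NULL) {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  feat_cols <- setdiff(names(features), c("label", "subject", "window_start"))
  x <- as.matrix(features[, feat_cols, drop = FALSE])
  yl <- factor(features$label)
  backend <- classifier_backend(classifier, config)

  cv <- crossval_protocol(yl, subjects = features$subject, folds = folds,
                          seed = seed)
  pred <- factor(rep(NA_character_, nrow(x)), levels = levels(yl))
  for (f in seq_len(folds)) {
    tr <- cv$folds != f; te <- cv$folds == f
    pred[te] <- with_seed(seed * 100 + f,
                          backend(x[tr, , drop = FALSE], yl[tr],
                                  x[te, , drop = FALSE]))
  }
  cv_conf <- table(true = yl, predicted = pred)
  out <- list(cv_confusion = unclass(cv_conf),
              cv_metrics = multiclass_metrics(unclass(cv_conf)))

  if (!is.null(cv$subject_holdout) && length(cv$subject_holdout) >= 2L) {
    ho_true <- factor(character(0), levels = levels(yl))
    ho_pred <- factor(character(0), levels = levels(yl))
    for (s in names(cv$subject_holdout)) {
      sp <- cv$subject_holdout[[s]]
      p <- with_seed(seed + 7919L,
                     backend(x[sp$train, , drop = FALSE], yl[sp$train],
                             x[sp$test, , drop = FALSE]))
      ho_true <- c(ho_true, yl[sp$test]); ho_pred <- c(ho_pred, p)
    }
    ho_conf <- table(true = ho_true, predicted = ho_pred)
    out$holdout_confusion <- unclass(ho_conf)
    out$holdout_metrics <- multiclass_metrics(unclass(ho_conf))
  }
  out
}

classifier_backend <- function(classifier, config = NULL) {
  if (is.function(classifier)) {
    cfg <- config
    return(function(trx, trY, tex) classifier(trx, trY, tex, cfg))
  }
  classifier <- match.arg(tolower(classifier), c("mlp", "svm"))
  cfg <- config %||% classifier_config()[[classifier]]
  if (classifier == "mlp") {
    if (!requireNamespace("nnet", quietly = TRUE)) {
      stop("the MLP backend requires the 'nnet' package", call. = FALSE)
    }
    function(trx, trY, tex) {
      sc <- scale(trx)
      fit <- nnet::nnet(sc, class.ind(trY), size = cfg$hidden %||% 6,
                        maxit = cfg$epochs %||% 600, softmax = TRUE,
                        trace = FALSE, MaxNWts = 5000)
      tex <- scale(tex, center = attr(sc, "scaled:center"),
                   scale = attr(sc, "scaled:scale"))
      factor(levels(trY)[max.col(predict(fit, tex))], levels = levels(trY))
    }
  } else {
    if (!requireNamespace("e1071", quietly = TRUE)) {
      stop("the SVM backend requires the 'e1071' package", call. = FALSE)
    }
    function(trx, trY, tex) {
      fit <- e1071::svm(trx, trY, kernel = cfg$kernel %||% "polynomial",
                        degree = cfg$degree %||% 2, cost = cfg$cost %||% 1,
                        coef0 = cfg$coef0 %||% 1)
      predict(fit, tex)
    }
  }
}

class.ind <- function(y) {
  y <- factor(y)
  out <- matrix(0, length(y), nlevels(y),
                dimnames = list(NULL, levels(y)))
  out[cbind(seq_along(y), as.integer(y))] <- 1
  out
}
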