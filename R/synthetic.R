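#' Generate an exactly block-sparse vector with intra-block correlation
#'
#' Draws `k_active` blocks of a block partition uniformly at random and
#' fills each with a zero-mean stationary AR(1) Gaussian sequence
#' (`x_t = r x_{t-1} + sqrt(1 - r^2) e_t`, unit marginal variance, lag-1
#' correlation `r`), scaled by `amplitude`. All other entries are exactly
#' zero. Optionally adds white Gaussian noise calibrated to a target SNR in
#' dB relative to the clean vector.
#'
#' @param N vector length.
#' @param block_size,sizes partition specification (see [block_partition()]).
#' @param k_active number of active (nonzero) blocks, `0 <= k_active <= l`.
#' @param r intra-block AR(1) coefficient, `|r| <= 0.99`.
#' @param amplitude scale applied to active blocks.
#' @param noise_snr_db target SNR of the returned signal in dB, or `NULL`
#'   for no noise.
#' @param seed RNG seed.
#' @return List with `signal` (length N; noisy if requested), `clean`
#'   (noise-free), `support` (indices of truly nonzero entries),
#'   `active_blocks` (block ids), and `partition`.
#' @examples
#' g <- gen_block_sparse(N = 100, block_size = 10, k_active = 2, seed = 1)
#' all(g$signal[-g$support] == 0)
#' @export
gen_block_sparse <- function(N = 500, block_size = 20, sizes = NULL,
                             k_active = 3, r = 0.9, amplitude = 1,
                             noise_snr_db = NULL, seed = 0L) {
  part <- block_partition(N, block_size, sizes)
  k_active <- check_scalar_count(k_active, "k_active", min = 0)
  if (k_active > part$l) stop("`k_active` exceeds the number of blocks",
                              call. = FALSE)
  if (!is.numeric(r) || length(r) != 1L || abs(r) > 0.99) {
    stop("`r` must satisfy |r| <= 0.99", call. = FALSE)
  }
  with_seed(seed, {
    active <- sort(sample.int(part$l, k_active))
    x <- numeric(part$N)
    for (j in active) {
      h <- part$sizes[j]
      e <- rnorm(h)
      b <- numeric(h)
      b[1] <- e[1]
      if (h > 1) for (t in 2:h) b[t] <- r * b[t - 1] + sqrt(1 - r^2) * e[t]
      x[part$index[[j]]] <- amplitude * b
    }
    clean <- x
    if (!is.null(noise_snr_db)) {
      sig_pow <- mean(clean^2)
      noise_sd <- sqrt(sig_pow * 10^(-noise_snr_db / 10))
      x <- clean + rnorm(part$N, sd = noise_sd)
    }
    list(signal = x, clean = clean,
         support = which(clean != 0), active_blocks = active,
         partition = part)
  })
}

#' Gait signal class presets
#'
#' Parameter presets for [gen_gait_signal()] mapping each activity class to
#' a distinct fundamental step frequency and per-axis amplitude profile so
#' that windowed features can separate the classes. These are caricatures
#' tuned for class separability, not biomechanically validated waveforms:
#' walking variants near 1 Hz with three harmonics, stair activities near
#' 0.8 Hz with an enhanced vertical axis, running at 2.5 Hz, and sitting as
#' a near-DC low-noise signal.
#'
#' @return Named list of preset parameter lists (`step_freq`, `harmonics`,
#'   `amplitudes`, `jitter`, `noise_sd`).
#' @export
gait_presets <- function() {
  list(
    walk_forward = list(step_freq = 1.0, harmonics = 3,
                        amplitudes = c(0.35, 0.25, 0.6),
                        jitter = 0.05, noise_sd = 0.03),
    walk_left    = list(step_freq = 0.95, harmonics = 3,
                        amplitudes = c(0.45, 0.35, 0.55),
                        jitter = 0.05, noise_sd = 0.03),
    walk_right   = list(step_freq = 1.05, harmonics = 3,
                        amplitudes = c(0.3, 0.45, 0.55),
                        jitter = 0.05, noise_sd = 0.03),
    upstairs     = list(step_freq = 0.8, harmonics = 4,
                        amplitudes = c(0.25, 0.2, 0.85),
                        jitter = 0.07, noise_sd = 0.03),
    downstairs   = list(step_freq = 0.85, harmonics = 2,
                        amplitudes = c(0.3, 0.2, 0.95),
                        jitter = 0.08, noise_sd = 0.04),
    run          = list(step_freq = 2.5, harmonics = 3,
                        amplitudes = c(0.6, 0.5, 1.3),
                        jitter = 0.04, noise_sd = 0.05),
    sit          = list(step_freq = 0.1, harmonics = 1,
                        amplitudes = c(0.01, 0.01, 0.015),
                        jitter = 0.0, noise_sd = 0.008)
  )
}

#' Generate a quasi-periodic gait-like tri-axial acceleration signal
#'
#' Each axis is a sum of `harmonics` sinusoids at multiples of the step
#' frequency with random phases and 1/h amplitude decay, warped by
#' per-cycle duration jitter (each gait cycle's length is perturbed by a
#' uniform factor in `1 +/- jitter`), plus a constant per-axis offset
#' (gravity projection) and additive white Gaussian noise. Class presets
#' are available via [gait_presets()].
#'
#' @param duration signal duration in seconds.
#' @param sample_rate sampling rate in Hz (default 100).
#' @param class preset name from [gait_presets()]; individual parameters
#'   below override the preset.
#' @param step_freq fundamental step frequency in Hz.
#' @param harmonics number of harmonics per axis.
#' @param amplitudes length-3 per-axis amplitude scale (in g).
#' @param jitter per-cycle duration jitter fraction, `0 <= jitter < 0.5`.
#' @param noise_sd additive white noise standard deviation (g).
#' @param offsets per-axis constant offsets (g); default `c(0, 0, 1)`
#'   (gravity on the vertical axis).
#' @param seed RNG seed.
#' @return A 3 x T numeric matrix (rows ax, ay, az), T = `duration *
#'   sample_rate`, with attributes `sample_rate` and `activity`.
#' @examples
#' x <- gen_gait_signal(duration = 10, class = "walk_forward", seed = 1)
#' dim(x)   # 3 x 1000
#' @export
gen_gait_signal <- function(duration = 30, sample_rate = 100,
                            class = "walk_forward", step_freq = NULL,
                            harmonics = NULL, amplitudes = NULL,
                            jitter = NULL, noise_sd = NULL,
                            offsets = c(0, 0, 1), seed = 0L) {
  presets <- gait_presets()
  if (!class %in% names(presets)) {
    stop(sprintf("unknown class '%s'; available: %s", class,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  }
  p <- presets[[class]]
  step_freq <- step_freq %||% p$step_freq
  harmonics <- harmonics %||% p$harmonics
  amplitudes <- amplitudes %||% p$amplitudes
  jitter <- jitter %||% p$jitter
  noise_sd <- noise_sd %||% p$noise_sd
  if (duration <= 0 || sample_rate <= 0) {
    stop("`duration` and `sample_rate` must be positive", call. = FALSE)
  }
  if (jitter < 0 || jitter >= 0.5) stop("`jitter` must be in [0, 0.5)",
                                        call. = FALSE)
  T <- as.integer(round(duration * sample_rate))
  t <- (seq_len(T) - 1L) / sample_rate
  with_seed(seed, {
    # piecewise-linear phase: each cycle lasts (1/f) * (1 + jitter * U(-1,1))
    n_cycles <- ceiling(duration * step_freq) + 2L
    durations <- (1 / step_freq) * (1 + jitter * runif(n_cycles, -1, 1))
    bounds <- c(0, cumsum(durations))
    # phase in cycles at each sample time (linear within each cycle)
    cyc <- findInterval(t, bounds, rightmost.closed = TRUE)
    frac <- (t - bounds[cyc]) / durations[cyc]
    phase <- 2 * pi * (cyc - 1 + frac)
    out <- matrix(0, 3, T)
    for (a in 1:3) {
      sig <- numeric(T)
      for (h in seq_len(harmonics)) {
        sig <- sig + (1 / h) * sin(h * phase + runif(1, 0, 2 * pi))
      }
      out[a, ] <- offsets[a] + amplitudes[a] * sig + rnorm(T, sd = noise_sd)
    }
    rownames(out) <- c("ax", "ay", "az")
    attr(out, "sample_rate") <- sample_rate
    attr(out, "activity") <- class
    out
  })
}

#' Generate a labeled windowed feature dataset
#'
#' End-to-end fixture generator for the classification protocol: for each
#' class it simulates per-subject recordings, segments them into windows
#' (default 512 samples, 50% overlap), extracts the 12-dimensional feature
#' vector of [window_features()], and tags each row with its class label
#' and a synthetic subject id (enabling subject-level hold-out).
#'
#' @param classes character vector of preset names (see [gait_presets()]).
#' @param windows_per_class number of windows to produce per class.
#' @param subjects_per_class how many synthetic subjects share each class's
#'   windows.
#' @param window_length,overlap_fraction windowing parameters.
#' @param sample_rate sampling rate in Hz.
#' @param seed RNG seed.
#' @return Data frame with the 12 feature columns plus `label`, `subject`,
#'   `window_start`; `windows_per_class = 0` yields an empty table.
#' @examples
#' d <- gen_labeled_dataset(c("upstairs", "downstairs"),
#'                          windows_per_class = 10, seed = 1)
#' table(d$label)
#' @export
gen_labeled_dataset <- function(classes, windows_per_class = 100,
                                subjects_per_class = 10,
                                window_length = 512, overlap_fraction = 0.5,
                                sample_rate = 100, seed = 0L) {
  if (length(classes) < 2L) stop("at least 2 classes are required",
                                 call. = FALSE)
  windows_per_class <- check_scalar_count(windows_per_class,
                                          "windows_per_class", min = 0)
  subjects_per_class <- check_scalar_count(subjects_per_class,
                                           "subjects_per_class")
  rows <- list()
  if (windows_per_class > 0) {
    per_subject <- ceiling(windows_per_class / subjects_per_class)
    step <- window_length * (1 - overlap_fraction)
    need_T <- window_length + (per_subject - 1) * step
    duration <- ceiling((need_T + window_length) / sample_rate)
    for (ci in seq_along(classes)) {
      cls <- classes[ci]
      made <- 0L
      for (s in seq_len(subjects_per_class)) {
        if (made >= windows_per_class) break
        sig <- gen_gait_signal(duration = duration, sample_rate = sample_rate,
                               class = cls,
                               seed = seed * 10000 + ci * 100 + s)
        wins <- segment(sig, window_length, overlap_fraction)
        take <- min(per_subject, windows_per_class - made, length(wins))
        if (take < 1L) {
          stop("recording too short for the requested number of windows",
               call. = FALSE)
        }
        for (w in wins[seq_len(take)]) {
          f <- window_features(w)
          rows[[length(rows) + 1L]] <- c(
            as.list(f),
            list(label = cls, subject = sprintf("%s_subj%02d", cls, s),
                 window_start = w$start))
        }
        made <- made + take
      }
    }
  }
  if (length(rows) == 0L) {
    empty <- as.data.frame(matrix(numeric(0), 0, 12))
    names(empty) <- names(window_features(matrix(rnorm(12), 3)))
    empty$label <- character(0); empty$subject <- character(0)
    empty$window_start <- integer(0)
    return(empty)
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
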