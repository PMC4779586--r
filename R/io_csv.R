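#' Read and write canonical plain-text recordings
#'
#' The canonical on-disk form of a tri-axial recording is a CSV file with
#' header `t_or_index, ax, ay, az` (acceleration in g) preceded by optional
#' `# key: value` comment lines carrying metadata (`sample_rate`, `subject`,
#' `activity`, `trial`). `read_csv_recording()` validates the columns and
#' reports malformed cells with their line numbers.
#'
#' @param path file path.
#' @param rec a `gait_recording` (as returned by the readers) or a 3 x T
#'   numeric matrix.
#' @param sample_rate,subject,activity,trial metadata written to the header
#'   (overriding fields already present in `rec`).
#' @return `read_csv_recording()` returns a `gait_recording`: list with
#'   `acc` (3 x T matrix, rows ax/ay/az), `sample_rate`, `subject`,
#'   `activity`, `trial`. `write_csv_recording()` returns `path` invisibly.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' x <- gen_gait_signal(duration = 2, class = "walk_forward", seed = 1)
#' write_csv_recording(x, path, subject = "s01", activity = "walk_forward")
#' rec <- read_csv_recording(path)
#' dim(rec$acc)
#' @export
read_csv_recording <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(lines[ml], regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$",
                                       lines[ml]))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  body_start <- if (length(meta_lines)) max(meta_lines) + 1L else 1L
  df <- tryCatch(
    read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("cannot parse %s: %s", path,
                                     conditionMessage(e)), call. = FALSE))
  required <- c("ax", "ay", "az")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in required) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(vals))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric or non-finite value in column '%s' at data row %d (file line ~%d)",
                   path, col, bad[1], body_start + bad[1]), call. = FALSE)
    }
    df[[col]] <- vals
  }
  if (nrow(df) < 1L) stop(sprintf("%s: no data rows", path), call. = FALSE)
  acc <- t(as.matrix(df[, required]))
  rownames(acc) <- required
  new_gait_recording(acc,
    sample_rate = as.numeric(meta$sample_rate %||% NA),
    subject = meta$subject %||% NA_character_,
    activity = meta$activity %||% NA_character_,
    trial = suppressWarnings(as.integer(meta$trial %||% NA)))
}

new_gait_recording <- function(acc, sample_rate = NA_real_,
                               subject = NA_character_,
                               activity = NA_character_, trial = NA_integer_) {
  structure(list(acc = acc, sample_rate = sample_rate, subject = subject,
                 activity = activity, trial = trial),
            class = "gait_recording")
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording> %d samples @ %s Hz, subject=%s activity=%s trial=%s\n",
              ncol(x$acc), format(x$sample_rate), x$subject, x$activity,
              format(x$trial)))
  invisible(x)
}

#' @rdname read_csv_recording
#' @export
write_csv_recording <- function(rec, path, sample_rate = NULL, subject = NULL,
                                activity = NULL, trial = NULL) {
  if (inherits(rec, "gait_recording")) {
    acc <- rec$acc
    sample_rate <- sample_rate %||% rec$sample_rate
    subject <- subject %||% rec$subject
    activity <- activity %||% rec$activity
    trial <- trial %||% rec$trial
  } else {
    acc <- as_triaxial(rec)
    sample_rate <- sample_rate %||% attr(rec, "sample_rate")
    activity <- activity %||% attr(rec, "activity")
  }
  con <- file(path, "w"); on.exit(close(con))
  hdr <- c(sample_rate = sample_rate, subject = subject, activity = activity,
           trial = trial)
  for (k in names(hdr)) {
    if (!is.null(hdr[[k]]) && !is.na(hdr[[k]])) {
      writeLines(sprintf("# %s: %s", k, hdr[[k]]), con)
    }
  }
  writeLines("# columns: t_or_index (0-based sample index), ax, ay, az [g]",
             con)
  df <- data.frame(t_or_index = seq_len(ncol(acc)) - 1L,
                   ax = acc[1, ], ay = acc[2, ], az = acc[3, ])
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
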