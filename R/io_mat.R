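# Minimal MATLAB level-5 container support: enough of the format (numeric
# and character arrays, little-endian, plain or zlib-compressed elements) to
# read hip-worn activity recordings stored as a T x 6 sensor matrix, and to
# write small fixture files. Cell arrays, structs, sparse and complex data
# are out of scope and fail with a descriptive error.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MI_UTF8 <- 16L; MI_UTF16 <- 17L
MX_CHAR <- 4L; MX_DOUBLE <- 6L; MX_SINGLE <- 7L
MX_INT8 <- 8L; MX_UINT8 <- 9L; MX_INT16 <- 10L; MX_UINT16 <- 11L
MX_INT32 <- 12L; MX_UINT32 <- 13L

read_mi_data <- function(raw, type, nbytes) {
  n <- length(raw)
  switch(as.character(type),
    "1" = readBin(raw, "integer", n, size = 1, signed = TRUE),
    "2" = readBin(raw, "integer", n, size = 1, signed = FALSE),
    "3" = readBin(raw, "integer", n %/% 2, size = 2, signed = TRUE,
                  endian = "little"),
    "4" = readBin(raw, "integer", n %/% 2, size = 2, signed = FALSE,
                  endian = "little"),
    "5" = readBin(raw, "integer", n %/% 4, size = 4, endian = "little"),
    "6" = readBin(raw, "integer", n %/% 4, size = 4, endian = "little"),
    "7" = readBin(raw, "double", n %/% 4, size = 4, endian = "little"),
    "9" = readBin(raw, "double", n %/% 8, size = 8, endian = "little"),
    "16" = utf8ToInt(rawToChar(raw)),
    stop(sprintf("unsupported MAT data type %d", type), call. = FALSE)
  )
}

# Parse one tagged element starting at offset `pos` (1-based) of `raw`.
# Returns list(type, data_raw, next_pos).
parse_element <- function(raw, pos) {
  type_word <- readBin(raw[pos:(pos + 3)], "integer", 1, size = 4,
                       endian = "little")
  small_size <- bitwAnd(bitwShiftR(type_word, 16L), 0xFFFFL)
  if (small_size > 0L) {             # small data element: data in tag bytes
    type <- bitwAnd(type_word, 0xFFFFL)
    data <- raw[(pos + 4):(pos + 3 + small_size)]
    return(list(type = type, data = data, next_pos = pos + 8L))
  }
  nbytes <- readBin(raw[(pos + 4):(pos + 7)], "integer", 1, size = 4,
                    endian = "little")
  data <- if (nbytes > 0) raw[(pos + 8):(pos + 7 + nbytes)] else raw(0)
  pad <- (8 - (nbytes %% 8)) %% 8
  if (type_word != MI_COMPRESSED) {
    # compressed elements are not padded in some writers; skip pad otherwise
    nbytes <- nbytes + pad
  }
  list(type = type_word, data = data, next_pos = pos + 8L + nbytes)
}

parse_matrix_element <- function(data) {
  pos <- 1L
  flags <- parse_element(data, pos); pos <- flags$next_pos
  flag_words <- readBin(flags$data, "integer", 2, size = 4, endian = "little")
  cls <- bitwAnd(flag_words[1], 0xFFL)
  dims_el <- parse_element(data, pos); pos <- dims_el$next_pos
  dims <- read_mi_data(dims_el$data, MI_INT32, length(dims_el$data))
  name_el <- parse_element(data, pos); pos <- name_el$next_pos
  name <- rawToChar(name_el$data[name_el$data != as.raw(0)])
  if (!cls %in% c(MX_CHAR, MX_DOUBLE, MX_SINGLE, MX_INT8, MX_UINT8,
                  MX_INT16, MX_UINT16, MX_INT32, MX_UINT32)) {
    return(list(name = name, value = NULL,
                note = sprintf("unsupported array class %d", cls)))
  }
  real_el <- parse_element(data, pos)
  vals <- read_mi_data(real_el$data, real_el$type, length(real_el$data))
  if (cls == MX_CHAR) {
    value <- intToUtf8(vals[vals != 0])
  } else {
    value <- array(as.numeric(vals), dim = dims)
    if (length(dims) == 2L) value <- matrix(value, dims[1], dims[2])
  }
  list(name = name, value = value, note = NULL)
}

#' Read a MATLAB level-5 container file
#'
#' Parses the little-endian MAT v5 format, including zlib-compressed
#' elements, returning numeric arrays and character strings by variable
#' name. Unsupported variable classes (cells, structs, sparse, complex)
#' are skipped with their names recorded in the `skipped` attribute.
#'
#' @param path file path.
#' @return Named list of variables (numeric matrices/arrays and strings).
#' @export
read_mat5 <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 128L) stop(sprintf("%s: too short to be a MAT v5 file",
                                       path), call. = FALSE)
  endian_tag <- rawToChar(raw[127:128])
  if (endian_tag == "MI") {
    stop(sprintf("%s: big-endian MAT files are not supported", path),
         call. = FALSE)
  }
  if (endian_tag != "IM") {
    stop(sprintf("%s: not a MAT v5 file (bad endian indicator '%s'); v4 and v7.3/HDF5 containers are not supported",
                 path, endian_tag), call. = FALSE)
  }
  pos <- 129L
  out <- list(); skipped <- character(0)
  while (pos + 7L <= length(raw)) {
    el <- parse_element(raw, pos)
    pos <- el$next_pos
    payload <- el$data
    type <- el$type
    if (type == MI_COMPRESSED) {
      payload <- memDecompress(payload, type = "gzip")
      inner <- parse_element(payload, 1L)
      type <- inner$type
      payload <- inner$data
    }
    if (type != MI_MATRIX) next
    parsed <- parse_matrix_element(payload)
    if (is.null(parsed$value)) skipped <- c(skipped, parsed$name)
    else out[[parsed$name]] <- parsed$value
  }
  attr(out, "skipped") <- skipped
  out
}

# Write a MAT v5 file from a named list of numeric matrices and strings.
# Internal: used to build test fixtures programmatically.
write_mat5 <- function(vars, path) {
  stopifnot(is.list(vars), !is.null(names(vars)), all(nzchar(names(vars))))
  con <- file(path, "wb"); on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by gaitcs")
  header <- charToRaw(formatC(desc, width = -116))
  header <- c(header, rep(as.raw(0x20), 116 - length(header)))[1:116]
  writeBin(header, con)
  writeBin(rep(as.raw(0), 8), con)                      # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)                  # version 0x0100
  writeBin(charToRaw("IM"), con)

  pad8 <- function(r) c(r, rep(as.raw(0), (8 - (length(r) %% 8)) %% 8))
  tag <- function(type, nbytes) {
    c(writeBin(as.integer(type), raw(), size = 4, endian = "little"),
      writeBin(as.integer(nbytes), raw(), size = 4, endian = "little"))
  }
  element <- function(type, payload) c(tag(type, length(payload)), pad8(payload))

  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (is.character(v)) {
      stopifnot(length(v) == 1L)
      codes <- utf8ToInt(v)
      dims <- c(1L, length(codes))
      cls <- MX_CHAR
      data_el <- element(MI_UINT16,
                         writeBin(as.integer(codes), raw(), size = 2,
                                  endian = "little"))
    } else {
      v <- as.matrix(v)
      dims <- dim(v)
      cls <- MX_DOUBLE
      data_el <- element(MI_DOUBLE,
                         writeBin(as.numeric(v), raw(), size = 8,
                                  endian = "little"))
    }
    flags <- element(MI_UINT32,
                     writeBin(as.integer(c(cls, 0L)), raw(), size = 4,
                              endian = "little"))
    dims_el <- element(MI_INT32,
                       writeBin(as.integer(dims), raw(), size = 4,
                                endian = "little"))
    name_el <- element(MI_INT8, charToRaw(nm))
    body <- c(flags, dims_el, name_el, data_el)
    writeBin(c(tag(MI_MATRIX, length(body)), body), con)
  }
  invisible(path)
}

#' Read a hip-worn activity recording from a MATLAB container
#'
#' Reads recordings in the layout used by public hip-worn inertial activity
#' datasets: a MAT v5 file holding a T x 6 numeric variable (columns 1-3:
#' tri-axial acceleration in g, columns 4-6: gyroscope in dps), typically
#' named `sensor_readings`, alongside optional metadata variables
#' `subject`, `activity`, `trial`, and `sr` (sample rate, Hz; defaults to
#' 100 when absent). Only the acceleration channels are retained.
#'
#' @param path file path.
#' @param var name of the sensor variable; when `NULL` the reader uses
#'   `sensor_readings` if present, otherwise the unique numeric variable
#'   with at least 6 columns.
#' @return A `gait_recording` (see [read_csv_recording()]).
#' @export
read_usc_had <- function(path, var = NULL) {
  vars <- read_mat5(path)
  pick <- NULL
  if (!is.null(var)) {
    if (is.null(vars[[var]])) {
      stop(sprintf("%s: variable '%s' not found (variables: %s)", path, var,
                   paste(names(vars), collapse = ", ")), call. = FALSE)
    }
    pick <- vars[[var]]
  } else if (!is.null(vars$sensor_readings)) {
    pick <- vars$sensor_readings
  } else {
    numeric_6col <- Filter(function(v) is.numeric(v) && is.matrix(v) &&
                             ncol(v) >= 6L, vars)
    if (length(numeric_6col) != 1L) {
      stop(sprintf("%s: no unambiguous 6-column sensor variable found (variables: %s)",
                   path, paste(names(vars), collapse = ", ")), call. = FALSE)
    }
    pick <- numeric_6col[[1]]
  }
  if (!is.numeric(pick) || !is.matrix(pick)) {
    stop(sprintf("%s: sensor variable is not a numeric matrix", path),
         call. = FALSE)
  }
  if (ncol(pick) < 6L && nrow(pick) >= 6L) pick <- t(pick)  # 6 x T dialect
  if (ncol(pick) < 6L) {
    stop(sprintf("%s: sensor variable has %d column(s); expected >= 6",
                 path, ncol(pick)), call. = FALSE)
  }
  if (nrow(pick) < 1L) stop(sprintf("%s: sensor variable has no samples",
                                    path), call. = FALSE)
  acc <- t(pick[, 1:3, drop = FALSE])
  rownames(acc) <- c("ax", "ay", "az")
  as_scalar <- function(v) {
    if (is.null(v)) NA else if (is.character(v)) v else as.numeric(v)[1]
  }
  sr <- as_scalar(vars$sr)
  if (is.character(sr)) sr <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", sr)))
  new_gait_recording(
    acc,
    sample_rate = if (is.na(sr %||% NA)) 100 else sr,
    subject = as.character(as_scalar(vars$subject) %||% NA),
    activity = as.character(as_scalar(vars$activity) %||% NA),
    trial = suppressWarnings(as.integer(as_scalar(vars$trial) %||% NA)))
}
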