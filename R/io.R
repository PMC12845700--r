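# Minimal MAT-file (level 5) codec for uncompressed double matrices.
# Covers the DB1-style container (keys emg, stimulus, repetition); supports
# little-endian files, full and small data element formats, and the common
# numeric storage types. Not a general MAT reader.

mat5_type_size <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 2, `5` = 4, `6` = 4,
                    `9` = 8, `12` = 8, `13` = 8)

write_mat5 <- function(path, vars) {
  stopifnot(is.list(vars), !is.null(names(vars)), all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by frozemg on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  hdr <- charToRaw(desc)
  hdr <- c(hdr, rep(as.raw(0x20), 116 - length(hdr)))
  writeBin(hdr, con)
  writeBin(rep(as.raw(0), 8), con)                  # subsys data offset
  writeBin(as.raw(c(0x00, 0x01)), con)              # version 0x0100 (LE)
  writeBin(charToRaw("IM"), con)                    # endian indicator
  for (nm in names(vars)) {
    x <- vars[[nm]]
    if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1)
    storage.mode(x) <- "double"
    name_raw <- charToRaw(nm)
    name_pad <- (8 - length(name_raw) %% 8) %% 8
    data_bytes <- 8 * length(x)
    data_pad <- (8 - data_bytes %% 8) %% 8
    body_bytes <- 16 +                              # array flags
      8 + 8 +                                       # dimensions (2-D)
      8 + length(name_raw) + name_pad +             # name
      8 + data_bytes + data_pad                     # real data
    writeBin(as.integer(c(14L, body_bytes)), con, size = 4, endian = "little")
    writeBin(as.integer(c(6L, 8L)), con, size = 4, endian = "little")
    writeBin(as.integer(c(6L, 0L)), con, size = 4, endian = "little")  # mxDOUBLE
    writeBin(as.integer(c(5L, 8L)), con, size = 4, endian = "little")
    writeBin(as.integer(dim(x)), con, size = 4, endian = "little")
    writeBin(as.integer(c(1L, length(name_raw))), con, size = 4,
             endian = "little")
    writeBin(name_raw, con)
    if (name_pad) writeBin(rep(as.raw(0), name_pad), con)
    writeBin(as.integer(c(9L, data_bytes)), con, size = 4, endian = "little")
    writeBin(as.vector(x), con, size = 8, endian = "little")
    if (data_pad) writeBin(rep(as.raw(0), data_pad), con)
  }
  invisible(path)
}

# read one sub-element tag, handling the small data element format;
# returns list(type, nbytes, small_data or NULL)
mat5_read_tag <- function(con) {
  w1 <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(w1) == 0) return(NULL)
  upper <- bitwAnd(bitwShiftR(w1, 16), 0xFFFF)
  if (upper != 0) {
    nbytes <- upper
    type <- bitwAnd(w1, 0xFFFF)
    data <- readBin(con, "raw", 4)
    list(type = type, nbytes = nbytes, small = data[seq_len(nbytes)])
  } else {
    nbytes <- readBin(con, "integer", 1, size = 4, endian = "little")
    list(type = w1, nbytes = nbytes, small = NULL)
  }
}

mat5_decode_numeric <- function(raw, type) {
  sz <- mat5_type_size[as.character(type)]
  if (is.na(sz)) stop("unsupported MAT data type: ", type)
  n <- length(raw) %/% sz
  what <- if (type == 9) "double" else "integer"
  signed <- !(type %in% c(2, 4, 6, 13))
  as.numeric(readBin(raw, what, n, size = sz, signed = signed || sz >= 4,
                     endian = "little"))
}

mat5_read_subelement <- function(con) {
  tag <- mat5_read_tag(con)
  if (is.null(tag)) return(NULL)
  if (!is.null(tag$small)) {
    raw <- tag$small
  } else {
    raw <- readBin(con, "raw", tag$nbytes)
    pad <- (8 - tag$nbytes %% 8) %% 8
    if (pad) readBin(con, "raw", pad)
  }
  list(type = tag$type, raw = raw)
}

read_mat5 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 124)
  readBin(con, "raw", 2)                              # version
  endian <- rawToChar(readBin(con, "raw", 2))
  if (endian != "IM") stop("only little-endian MAT files are supported")
  out <- list()
  repeat {
    tag <- mat5_read_tag(con)
    if (is.null(tag)) break
    if (tag$type == 15)
      stop("compressed MAT elements are not supported")
    if (tag$type != 14) {                             # skip non-matrix element
      skip <- tag$nbytes + (8 - tag$nbytes %% 8) %% 8
      if (is.null(tag$small)) readBin(con, "raw", skip)
      next
    }
    end_pos <- seek(con, NA) + tag$nbytes
    flags <- mat5_read_subelement(con)
    dims <- mat5_read_subelement(con)
    name <- mat5_read_subelement(con)
    data <- mat5_read_subelement(con)
    dims_v <- readBin(dims$raw, "integer", length(dims$raw) %/% 4, size = 4,
                      endian = "little")
    nm <- rawToChar(name$raw[name$raw != as.raw(0)])
    vals <- mat5_decode_numeric(data$raw, data$type)
    out[[nm]] <- matrix(vals, nrow = dims_v[1], ncol = dims_v[2])
    seek(con, end_pos)
  }
  out
}

#' Write a recording to disk
#'
#' Emits a recording in the DB1-style container: either a MAT-file with
#' keys `emg` (T x channels), `stimulus` and `repetition` (T x 1), or a
#' tab-delimited text file with columns `emg_1..emg_C`, `stimulus`,
#' `repetition`. Both round-trip through [load_recording()].
#'
#' @param rec a `recording`.
#' @param path output path.
#' @param dialect `"mat"` or `"delimited"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dialect = c("mat", "delimited")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(rec, "recording"))
  if (dialect == "mat") {
    write_mat5(path, list(emg = t(rec$emg),
                          stimulus = as.numeric(rec$labels),
                          repetition = as.numeric(rec$repetitions)))
  } else {
    df <- as.data.frame(t(rec$emg))
    names(df) <- paste0("emg_", seq_len(nrow(rec$emg)))
    df$stimulus <- rec$labels
    df$repetition <- rec$repetitions
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Load a recording from disk
#'
#' Reads the DB1-style MAT container (keys `emg`, `stimulus`, `repetition`)
#' or the equivalent tab-delimited text file written by [write_recording()].
#'
#' @param path input file.
#' @param dialect `"mat"` or `"delimited"`.
#' @param fs sampling rate in Hz (the container does not store it).
#' @return a `recording` with `emg` as channels x T.
#' @export
load_recording <- function(path, dialect = c("mat", "delimited"), fs = 100) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "mat") {
    vars <- read_mat5(path)
    for (key in c("emg", "stimulus", "repetition"))
      if (is.null(vars[[key]]))
        stop("MAT file is missing required key '", key, "'")
    emg <- vars$emg; stim <- as.integer(vars$stimulus)
    reps <- as.integer(vars$repetition)
  } else {
    df <- tryCatch(read.table(path, header = TRUE, sep = "\t"),
                   error = function(e) stop("cannot parse delimited file: ",
                                            conditionMessage(e)))
    emg_cols <- grep("^emg_", names(df), value = TRUE)
    if (length(emg_cols) == 0) stop("delimited file is missing 'emg_*' columns")
    for (key in c("stimulus", "repetition"))
      if (!key %in% names(df))
        stop("delimited file is missing required column '", key, "'")
    if (!all(vapply(df[emg_cols], is.numeric, logical(1))))
      stop("non-numeric data in emg columns")
    emg <- as.matrix(df[emg_cols])
    stim <- as.integer(df$stimulus); reps <- as.integer(df$repetition)
  }
  if (!is.numeric(emg)) stop("non-numeric emg data")
  if (length(stim) != nrow(emg))
    stop("'stimulus' length does not match emg rows")
  if (length(reps) != nrow(emg))
    stop("'repetition' length does not match emg rows")
  structure(list(emg = t(emg), fs = fs, labels = stim, repetitions = reps,
                 truth = NULL, rep_blocks = NULL, config = NULL),
            class = "recording")
}
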