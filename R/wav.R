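# Minimal RIFF/WAVE reader and writer (PCM 16/24/32 and IEEE float32), enough
# for exchanging calibrated mono stimuli with external tools.

#' Read a WAV file
#'
#' Supports 16/24/32-bit PCM and 32-bit IEEE float. Multi-channel files are
#' reduced to the first channel with a warning. PCM samples are scaled to
#' \[-1, 1).
#'
#' @param path path to a RIFF/WAVE file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("cannot read WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || !nzchar(id)) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        format = readBin(body[1:2], "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(body[3:4], "integer", 1, 2, endian = "little", signed = FALSE),
        fs = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, 2, endian = "little", signed = FALSE))
      if (fmt$format == 65534L && sz >= 40) {  # WAVE_FORMAT_EXTENSIBLE
        fmt$format <- readBin(body[25:26], "integer", 1, 2, endian = "little",
                              signed = FALSE)
      }
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + sz %% 2)
      next
    }
    if (sz %% 2 == 1) readBin(con, "raw", 1)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV file: ", path)
  bytes <- fmt$bits %/% 8
  n <- length(data_raw) %/% bytes
  if (fmt$format == 1L) {
    if (fmt$bits == 16L) {
      s <- readBin(data_raw, "integer", n, 2, signed = TRUE, endian = "little") / 2^15
    } else if (fmt$bits == 24L) {
      m <- matrix(as.integer(data_raw[seq_len(n * 3)]), nrow = 3)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v[v >= 2^23] <- v[v >= 2^23] - 2^24
      s <- v / 2^23
    } else if (fmt$bits == 32L) {
      s <- readBin(data_raw, "integer", n, 4, signed = TRUE, endian = "little") / 2^31
    } else stop("unsupported PCM bit depth in ", path, ": ", fmt$bits)
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    s <- readBin(data_raw, "double", n, 4, endian = "little")
  } else {
    stop("unsupported WAV encoding in ", path, " (format ", fmt$format,
         ", ", fmt$bits, " bits)")
  }
  if (fmt$channels > 1L) {
    warning("multi-channel WAV '", path, "': taking first channel")
    s <- s[seq(1, length(s), by = fmt$channels)]
  }
  audio_signal(s, fmt$fs, label = basename(path))
}

#' Write a WAV file
#'
#' @param x an [audio_signal()].
#' @param path output path.
#' @param format `"float32"` (default, preserves calibration exactly within
#'   single precision) or `"pcm16"` (samples clipped to \[-1, 1)).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, format = c("float32", "pcm16")) {
  stopifnot(inherits(x, "audio_signal"))
  format <- match.arg(format)
  n <- length(x$samples)
  bytes <- if (format == "float32") 4L else 2L
  fmt_code <- if (format == "float32") 3L else 1L
  data_size <- n * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")  # mono
  writeBin(as.integer(x$fs), con, 4, endian = "little")
  writeBin(as.integer(x$fs * bytes), con, 4, endian = "little")
  writeBin(as.integer(bytes), con, 2, endian = "little")
  writeBin(as.integer(8L * bytes), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (format == "float32") {
    writeBin(x$samples, con, 4, endian = "little")
  } else {
    v <- as.integer(round(pmax(pmin(x$samples, 1 - 2^-15), -1) * 2^15))
    writeBin(v, con, 2, endian = "little")
  }
  invisible(path)
}
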