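# Minimal RIFF/WAVE PCM reader and writer. Only what the recorders in scope
# produce is supported: uncompressed integer PCM, mono or multichannel,
# 8/16/24/32-bit. Samples are exchanged as doubles in [-1, 1].

#' Read a PCM WAV file
#'
#' @param path Path to a RIFF/WAVE file containing uncompressed integer PCM.
#' @param channel Channel to return when the file is multichannel (default 1).
#' @return A list with `samples` (double vector scaled to `[-1, 1]`),
#'   `sample_rate` (Hz), `bit_depth` and `n_channels`.
#' @export
read_wav <- function(path, channel = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("not a RIFF file")
  readBin(con, "integer", 1L, size = 4L, endian = "little") # chunk size
  if (!identical(readChar(con, 4L, useBytes = TRUE), "WAVE")) {
    abort("not a WAVE file")
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1L, size = 2L, endian = "little"),
        n_channels   = readBin(con, "integer", 1L, size = 2L, endian = "little"),
        sample_rate  = readBin(con, "integer", 1L, size = 4L, endian = "little"),
        byte_rate    = readBin(con, "integer", 1L, size = 4L, endian = "little"),
        block_align  = readBin(con, "integer", 1L, size = 2L, endian = "little"),
        bit_depth    = readBin(con, "integer", 1L, size = 2L, endian = "little")
      )
      extra <- size - 16L
      if (extra > 0L) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) readBin(con, "raw", 1L) # pad byte
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) abort("missing fmt or data chunk")
  if (fmt$audio_format != 1L) abort("only uncompressed PCM (format tag 1) is supported")
  bytes <- fmt$bit_depth %/% 8L
  n <- length(data_raw) %/% (bytes * fmt$n_channels)
  if (bytes == 3L) {
    # 24-bit: assemble little-endian triplets by hand
    m <- matrix(as.integer(data_raw[seq_len(n * fmt$n_channels * 3L)]), nrow = 3L)
    vals <- m[1L, ] + 256L * m[2L, ] + 65536L * m[3L, ]
    vals <- ifelse(vals >= 2^23, vals - 2^24, vals)
  } else {
    vals <- readBin(data_raw, "integer",
      n = n * fmt$n_channels, size = bytes,
      signed = bytes > 1L, endian = "little"
    )
    if (bytes == 1L) vals <- vals - 128L # 8-bit WAV is unsigned
  }
  full_scale <- 2^(8L * bytes - 1L)
  x <- vals / full_scale
  if (fmt$n_channels > 1L) {
    x <- x[seq(channel, length(x), by = fmt$n_channels)]
  }
  list(
    samples = x, sample_rate = fmt$sample_rate,
    bit_depth = fmt$bit_depth, n_channels = fmt$n_channels
  )
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Double vector in `[-1, 1]`; values outside are clipped.
#' @param path Output path.
#' @param sample_rate Sampling rate in Hz (default 48000).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 48000L) {
  stopifnot(is.numeric(samples), length(samples) > 0L)
  x <- pmin(pmax(samples, -1), 1)
  ints <- as.integer(round(x * 32767))
  data_size <- length(ints) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little") # PCM
  writeBin(1L, con, size = 2L, endian = "little") # mono
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little") # block align
  writeBin(16L, con, size = 2L, endian = "little") # bit depth
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4L, endian = "little")
  writeBin(ints, con, size = 2L, endian = "little")
  invisible(path)
}
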