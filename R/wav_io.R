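#' Read a WAV file
#'
#' Parses a RIFF/WAVE file and returns a mono [audio_signal()]. Integer PCM
#' (8/16/24/32-bit) and IEEE float (32/64-bit) encodings are supported;
#' integer samples are scaled to \[-1, 1\] by the format's full-scale value
#' (e.g. 32768 for 16-bit). Multi-channel audio is averaged to mono.
#'
#' @param path Path to a WAV file.
#' @return An `audio_signal`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stopf("WAV file not found: '%s'", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stopf("'%s' is not a RIFF/WAVE file", path)
  readBin(con, "integer", 1, 4, endian = "little")  # overall size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stopf("'%s' is not a RIFF/WAVE file", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- .parse_fmt(body, path)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + (size %% 2))  # skip (chunks are word-aligned)
      next
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stopf("'%s': no fmt chunk found", path)
  if (is.null(data_raw)) stopf("'%s': no data chunk found", path)

  x <- .decode_samples(data_raw, fmt, path)
  n_ch <- fmt$channels
  if (n_ch > 1) {
    usable <- (length(x) %/% n_ch) * n_ch
    x <- rowMeans(matrix(x[seq_len(usable)], ncol = n_ch, byrow = TRUE))
  }
  audio_signal(x, fmt$rate)
}

.parse_fmt <- function(body, path) {
  u16 <- function(i) sum(as.integer(body[i + 0:1]) * c(1, 256))
  u32 <- function(i) sum(as.numeric(body[i + 0:3]) * 256^(0:3))
  tag <- u16(1)
  fmt <- list(format = tag, channels = u16(3), rate = u32(5), bits = u16(15))
  if (tag == 65534L) {  # WAVE_FORMAT_EXTENSIBLE: subformat GUID at offset 24
    if (length(body) >= 26) fmt$format <- u16(25)
  }
  if (!fmt$format %in% c(1L, 3L)) {
    stopf("'%s': unsupported WAV encoding (format tag %d); only PCM and IEEE float are supported",
          path, fmt$format)
  }
  fmt
}

.decode_samples <- function(raw, fmt, path) {
  n <- length(raw)
  if (fmt$format == 3L) {  # IEEE float
    if (!fmt$bits %in% c(32L, 64L)) stopf("'%s': unsupported float width %d", path, fmt$bits)
    return(readBin(raw, "double", n %/% (fmt$bits / 8), fmt$bits / 8,
                   endian = "little"))
  }
  switch(as.character(fmt$bits),
    "8"  = (as.integer(readBin(raw, "integer", n, 1, signed = FALSE)) - 128) / 128,
    "16" = readBin(raw, "integer", n %/% 2, 2, signed = TRUE, endian = "little") / 32768,
    "24" = .decode_pcm24(raw) / 8388608,
    "32" = readBin(raw, "integer", n %/% 4, 4, endian = "little") / 2147483648,
    stopf("'%s': unsupported PCM bit depth %d", path, fmt$bits)
  )
}

.decode_pcm24 <- function(raw) {
  m <- matrix(as.numeric(raw[seq_len((length(raw) %/% 3) * 3)]), nrow = 3)
  v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
  ifelse(v >= 8388608, v - 16777216, v)
}

#' Write a 16-bit PCM WAV file
#'
#' Samples are clipped to \[-1, 1\] and quantized to 16-bit integers
#' (positive full scale 32767).
#'
#' @param signal An `audio_signal`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- pmin(pmax(signal$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  rate <- as.integer(round(signal$rate))
  n_bytes <- length(pcm) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")            # PCM
  writeBin(1L, con, 2, endian = "little")            # mono
  writeBin(rate, con, 4, endian = "little")
  writeBin(rate * 2L, con, 4, endian = "little")     # byte rate
  writeBin(2L, con, 2, endian = "little")            # block align
  writeBin(16L, con, 2, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
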