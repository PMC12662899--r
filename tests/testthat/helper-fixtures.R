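# Shared fixtures: tiny signals and hand-built WAV files.

tone <- function(freq_hz, dur_s = 1, rate = 16000, amp = 0.5) {
  audio_signal(amp * sin(2 * pi * freq_hz * (0:(dur_s * rate - 1)) / rate),
               rate)
}

# Minimal 16-bit PCM WAV writer supporting multiple channels, independent
# of the package's write_wav (interleaved `channels` is a matrix with one
# column per channel, integer sample values).
write_pcm16_wav <- function(path, pcm, rate, n_channels = 1L) {
  pcm <- as.integer(pcm)
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(n_channels), con, 2, endian = "little")
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * 2L * n_channels), con, 4, endian = "little")
  writeBin(as.integer(2L * n_channels), con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  path
}

# Random disjoint swallow-like event lists (durations 0.3-0.9 s, gaps
# >= 0.5 s) inside [0, span_s].
random_events <- function(n, span_s = 30) {
  durs <- runif(n, 0.3, 0.9)
  free <- span_s - sum(durs) - (n - 1) * 0.5 - 0.5
  stopifnot(free > 0)
  u <- sort(runif(n, 0, free))
  starts <- 0.25 + u + c(0, cumsum(durs[-n] + 0.5))
  event_list(starts, starts + durs, "swallow")
}
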