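# Frame slicing and the log-Mel / zero-crossing-rate front end.
#
# Frames are 0.96 s with a 50% overlap (hop 0.48 s) at 16 kHz, i.e. 15360
# samples with a 7680-sample hop. Each frame is turned into a 96 x 64
# log-Mel patch (25 ms STFT window, 10 ms hop, 64 mel bands over
# 125-7500 Hz, log offset 0.001) matching the published front-end
# convention of the pretrained audio-classification network the embedding
# backend emulates, plus a scalar zero-crossing rate.


#' Slice a 16 kHz recording into overlapping analysis frames
#'
#' Frames are 0.96 s (15360 samples) advanced by 0.48 s (50% overlap). The
#' final partial frame is zero-padded to full length so the tail of the
#' recording stays analysable. Frame count is
#' `1 + ceiling(max(n - 15360, 0) / 7680)`.
#'
#' @param signal An [audio_signal()] at 16000 Hz (use [resample_audio()]
#'   first if needed).
#' @param frame_s Frame length in seconds (default 0.96).
#' @param overlap Fractional overlap between consecutive frames (default 0.5).
#' @return A list of class `frame_set`: `frames` (matrix, one row per frame),
#'   `starts_s` (frame start times), `frame_s`, `hop_s`, `n_samples`.
#' @export
frame_signal <- function(signal, frame_s = FRAME_LEN_S, overlap = 0.5) {
  stopifnot(inherits(signal, "audio_signal"))
  if (signal$rate != FRAME_RATE_HZ) {
    stopf("frame_signal expects a %d Hz signal (got %g Hz); resample_audio() first",
          FRAME_RATE_HZ, signal$rate)
  }
  n <- length(signal$samples)
  if (n == 0) stopf("cannot frame an empty signal")
  flen <- as.integer(round(frame_s * signal$rate))
  hop <- as.integer(round(flen * (1 - overlap)))
  n_frames <- 1L + as.integer(ceiling(max(n - flen, 0) / hop))
  padded <- c(signal$samples, numeric((n_frames - 1L) * hop + flen - n))
  idx <- outer(seq_len(flen), (seq_len(n_frames) - 1L) * hop, `+`)
  frames <- t(matrix(padded[idx], nrow = flen))
  structure(list(frames = frames,
                 starts_s = (seq_len(n_frames) - 1L) * hop / signal$rate,
                 frame_s = flen / signal$rate,
                 hop_s = hop / signal$rate,
                 n_samples = n),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set: %d frames of %.2f s, hop %.2f s>\n",
              nrow(x$frames), x$frame_s, x$hop_s))
  invisible(x)
}

#' Log-Mel spectrogram patch of one analysis frame
#'
#' STFT with a 25 ms periodic Hann window and 10 ms hop; magnitude spectra
#' are pooled onto 64 triangular mel bands spanning 125-7500 Hz, then
#' compressed as `log(energy + 0.001)`. The frame tail is zero-padded so
#' exactly 96 STFT steps result, giving a 96 x 64 patch.
#'
#' @param frame_samples Numeric vector of exactly 15360 samples (16 kHz).
#' @return 96 x 64 numeric matrix (time steps x mel bands).
#' @export
log_mel <- function(frame_samples) {
  if (length(frame_samples) != FRAME_LEN) {
    stopf("log_mel expects exactly %d samples, got %d", FRAME_LEN,
          length(frame_samples))
  }
  # pad the tail so the 96th window fits: 400 + 95*160 = 15600 samples
  need <- STFT_WIN + (N_STFT_STEPS - 1L) * STFT_HOP
  x <- c(frame_samples, numeric(need - FRAME_LEN))
  win <- .hann_periodic(STFT_WIN)
  idx <- outer(seq_len(STFT_WIN), (seq_len(N_STFT_STEPS) - 1L) * STFT_HOP, `+`)
  seg <- matrix(x[idx], nrow = STFT_WIN) * win
  seg <- rbind(seg, matrix(0, STFT_NFFT - STFT_WIN, N_STFT_STEPS))
  spec <- abs(stats::mvfft(seg))[seq_len(STFT_NFFT / 2 + 1L), , drop = FALSE]
  mel <- t(spec) %*% .mel_filterbank()           # 96 x 64
  log(mel + LOG_OFFSET)
}

.hann_periodic <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

.hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
.mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel band edge frequencies of the front end
#'
#' Lower, center and upper frequencies (Hz) of the 64 triangular mel
#' filters spanning 125-7500 Hz.
#'
#' @return A data.frame with columns `lower_hz`, `center_hz`, `upper_hz`.
#' @export
mel_band_edges <- function() {
  m <- seq(.hz_to_mel(MEL_FMIN), .hz_to_mel(MEL_FMAX), length.out = N_MEL + 2L)
  f <- .mel_to_hz(m)
  data.frame(lower_hz = f[seq_len(N_MEL)],
             center_hz = f[seq_len(N_MEL) + 1L],
             upper_hz = f[seq_len(N_MEL) + 2L])
}

# 257 x 64 triangular filterbank on the FFT bin grid; cached after first use.
.mel_env <- new.env(parent = emptyenv())
.mel_filterbank <- function() {
  if (!is.null(.mel_env$fb)) return(.mel_env$fb)
  edges <- mel_band_edges()
  freqs <- (0:(STFT_NFFT / 2)) * FRAME_RATE_HZ / STFT_NFFT
  fb <- matrix(0, length(freqs), N_MEL)
  for (b in seq_len(N_MEL)) {
    lo <- edges$lower_hz[b]; ce <- edges$center_hz[b]; up <- edges$upper_hz[b]
    rise <- (freqs - lo) / (ce - lo)
    fall <- (up - freqs) / (up - ce)
    fb[, b] <- pmax(0, pmin(rise, fall))
  }
  .mel_env$fb <- fb
  fb
}

#' Zero-crossing rate of a frame
#'
#' Fraction of consecutive-sample pairs whose signs differ, with zero
#' counted as positive: `crossings / (length - 1)`, in \[0, 1\].
#'
#' @param frame_samples Numeric vector (length >= 2).
#' @return The zero-crossing rate.
#' @export
zcr <- function(frame_samples) {
  n <- length(frame_samples)
  if (n < 2) stopf("zcr needs at least 2 samples")
  s <- ifelse(frame_samples >= 0, 1L, -1L)
  sum(s[-1] != s[-n]) / (n - 1)
}

#' Per-frame front-end features for a whole recording
#'
#' Convenience wrapper: frames the signal and computes the log-Mel patch
#' and zero-crossing rate of every frame.
#'
#' @param signal An [audio_signal()] at 16 kHz.
#' @return A list of class `frame_features`: `patches` (list of 96 x 64
#'   matrices), `zcr` (numeric vector), `starts_s`, and the `frame_set`.
#' @export
frame_features <- function(signal) {
  fs <- frame_signal(signal)
  patches <- lapply(seq_len(nrow(fs$frames)), function(i) log_mel(fs$frames[i, ]))
  structure(list(patches = patches,
                 zcr = apply(fs$frames, 1, zcr),
                 starts_s = fs$starts_s,
                 frame_set = fs),
            class = "frame_features")
}
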