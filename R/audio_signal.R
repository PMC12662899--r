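#' Construct a mono audio signal
#'
#' The basic waveform container used throughout the package: a numeric
#' vector of dimensionless amplitudes together with its sample rate.
#'
#' @param samples Numeric vector of sample amplitudes (mono).
#' @param rate Sample rate in Hz (> 0).
#' @return An object of class `audio_signal` with elements `samples` and
#'   `rate`.
#' @examples
#' s <- audio_signal(sin(2 * pi * 440 * (0:15999) / 16000), 16000)
#' duration(s)
#' @export
audio_signal <- function(samples, rate) {
  if (!is.numeric(samples)) stopf("`samples` must be numeric")
  if (!is.null(dim(samples))) stopf("`samples` must be 1-D (mono)")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stopf("`rate` must be a single positive number (Hz)")
  }
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$rate, duration(x)))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param signal An `audio_signal`.
#' @return Length in seconds.
#' @export
duration <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  length(signal$samples) / signal$rate
}

#' Peak-normalize an audio signal
#'
#' Divides the waveform by its maximum absolute amplitude so that sample
#' values span \[-1, 1\] with the peak at exactly 1 in magnitude. An
#' all-zero signal is returned unchanged.
#'
#' @param signal An `audio_signal`.
#' @return The normalized `audio_signal`.
#' @export
normalize_amplitude <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  peak <- max(abs(signal$samples))
  if (peak == 0) return(signal)
  audio_signal(signal$samples / peak, signal$rate)
}

#' Resample an audio signal
#'
#' Band-limited (polyphase) sample-rate conversion via [signal::resample()].
#' The output length is `round(n * target_rate / rate)`. A signal already at
#' the target rate is returned unchanged.
#'
#' @param signal An `audio_signal`.
#' @param target_rate Target sample rate in Hz; default 16000, the rate the
#'   feature front end expects.
#' @return An `audio_signal` at `target_rate`.
#' @export
resample_audio <- function(signal, target_rate = 16000) {
  stopifnot(inherits(signal, "audio_signal"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0) {
    stopf("`target_rate` must be a single positive number (Hz)")
  }
  if (signal$rate == target_rate) return(signal)
  n_out <- round(length(signal$samples) * target_rate / signal$rate)
  # rational approximation of the conversion ratio for the polyphase filter
  fr <- .rational_ratio(target_rate, signal$rate)
  y <- signal::resample(signal$samples, fr[1], fr[2])
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, numeric(n_out - length(y)))
  audio_signal(y, target_rate)
}

# p/q in lowest terms for (possibly non-integer) rates.
.rational_ratio <- function(p, q, scale = 1000) {
  if (p %% 1 != 0 || q %% 1 != 0) {
    p <- round(p * scale); q <- round(q * scale)
  }
  g <- .gcd(p, q)
  c(p / g, q / g)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)
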