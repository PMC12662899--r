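# Synthetic cervical-auscultation recordings with gold annotations.
#
# Each recording emulates a one-minute clinical feeding observation:
# coloured background noise, 5-20 short broadband swallow bursts at a
# controlled band SNR, and distractor sounds (tonal hums, single loud
# clicks) that never overlap swallows and never appear in the gold event
# list. The swallow surrogate — 2-3 band-limited (300-3000 Hz) noise
# bursts with exponential-decay envelopes — is a separability surrogate,
# not a clinically realistic swallow.

SWALLOW_BAND_HZ <- c(300, 3000)

#' Simulation configuration
#'
#' @param duration_s Recording length in seconds (default 60, one
#'   clinical observation).
#' @param n_events Number of swallows; `NULL` draws uniformly from 5-20.
#' @param event_duration_range Swallow duration range in seconds.
#' @param min_gap_s Minimum gap between consecutive swallows.
#' @param snr_db Mean 300-3000 Hz band power inside swallow intervals
#'   relative to background, in dB.
#' @param distractor_rate Expected distractors per minute.
#' @param background List: `exponent` (spectral slope; amplitude ~
#'   f^-exponent, 0.5 = pink) and `level_db` (gain re the unit reference).
#' @param sample_rate Sample rate (Hz).
#' @param seed Integer seed; generation is deterministic per seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 60, n_events = NULL,
                       event_duration_range = c(0.3, 0.9), min_gap_s = 0.5,
                       snr_db = 10, distractor_rate = 2,
                       background = list(exponent = 0.5, level_db = 0),
                       sample_rate = 16000, seed = 1L) {
  stopifnot(duration_s > 0, all(event_duration_range > 0),
            event_duration_range[1] <= event_duration_range[2],
            min_gap_s >= 0, sample_rate > 0)
  structure(list(duration_s = duration_s, n_events = n_events,
                 event_duration_range = event_duration_range,
                 min_gap_s = min_gap_s, snr_db = snr_db,
                 distractor_rate = distractor_rate, background = background,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# coloured noise via spectral shaping: amplitude ~ f^-exponent
.coloured_noise <- function(n, exponent) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))  # guard DC
  shape <- pmin(f, n - f)^-exponent
  shape[1] <- 0
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

.bandpass <- function(x, rate, band = SWALLOW_BAND_HZ) {
  bf <- signal::butter(4, band / (rate / 2), type = "pass")
  signal::filtfilt(bf, x)
}

.band_power <- function(x, rate, band = SWALLOW_BAND_HZ) {
  mean(.bandpass(x, rate, band)^2)
}

#' Generate one synthetic labelled recording
#'
#' @param config A [sim_config()].
#' @return A list: `signal` (an [audio_signal()], peak-normalized) and
#'   `events` (the gold event list).
#' @export
generate_recording <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  rate <- config$sample_rate
  n <- as.integer(round(config$duration_s * rate))
  bg_rms <- 0.03  # unit reference level before the final peak normalization

  with_local_seed(config$seed, {
    n_ev <- config$n_events %||% sample(5:20, 1)
    events <- .place_events(n_ev, config)

    bg <- .coloured_noise(n, config$background$exponent) *
      bg_rms * 10^(config$background$level_db / 20)
    x <- bg
    p_bg <- .band_power(bg, rate)

    for (i in seq_len(nrow(events))) {
      burst <- .swallow_burst(events$start_s[i], events$end_s[i], rate)
      p_target <- (10^(config$snr_db / 10) - 1) * p_bg
      span <- burst$span
      p_now <- mean(burst$samples[span]^2)
      g <- sqrt(p_target / max(p_now, 1e-12))
      x[span] <- x[span] + g * burst$samples[span]
    }

    x <- x + .distractors(n, rate, config, events, bg_rms)
    rec <- normalize_amplitude(audio_signal(x, rate))
    list(signal = rec, events = events)
  })
}

# sequential random placement with edge margins and minimum gaps
.place_events <- function(n_ev, config) {
  if (n_ev == 0) return(event_list(numeric(), numeric(), character()))
  margin <- 0.25
  durs <- stats::runif(n_ev, config$event_duration_range[1],
                       config$event_duration_range[2])
  free <- config$duration_s - sum(durs) - (n_ev - 1) * config$min_gap_s -
    2 * margin
  if (free < 0) {
    stopf("cannot pack %d swallows of up to %.2f s with %.2f s gaps into %.1f s; use fewer events",
          n_ev, config$event_duration_range[2], config$min_gap_s,
          config$duration_s)
  }
  u <- sort(stats::runif(n_ev, 0, free))
  starts <- margin + u + c(0, cumsum(durs[-n_ev] + config$min_gap_s))
  event_list(round(starts, 3), round(starts + durs, 3), "swallow")
}

# 2-3 decaying band-limited noise bursts spanning one swallow interval
.swallow_burst <- function(start_s, end_s, rate) {
  n_total <- as.integer(round(end_s * rate)) - as.integer(round(start_s * rate))
  n_bursts <- sample(2:3, 1)
  env <- numeric(n_total)
  # bursts partition the interval; each decays over its own stretch
  cuts <- sort(stats::runif(n_bursts - 1, 0.25, 0.75))
  bounds <- round(c(0, cuts, 1) * n_total)
  for (b in seq_len(n_bursts)) {
    seg <- (bounds[b] + 1):bounds[b + 1]
    len <- length(seg)
    if (len < 8) next
    t_rel <- seq_len(len) / len
    env[seg] <- exp(-4 * t_rel) * stats::runif(1, 0.6, 1)
  }
  noise <- .bandpass(stats::rnorm(n_total), rate)
  samples <- numeric(as.integer(round(end_s * rate)))
  span <- (as.integer(round(start_s * rate)) + 1):length(samples)
  samples[span] <- noise * env
  list(samples = samples, span = span)
}

# tonal hums (200-500 Hz) and single loud clicks in swallow-free stretches
.distractors <- function(n, rate, config, events, bg_rms) {
  out <- numeric(n)
  n_d <- stats::rpois(1, config$distractor_rate * config$duration_s / 60)
  if (n_d == 0) return(out)
  busy <- events
  for (d in seq_len(n_d)) {
    is_hum <- d %% 2 == 1
    dur <- if (is_hum) stats::runif(1, 1, 2.5) else 0.005
    placed <- FALSE
    for (attempt in 1:50) {
      s <- stats::runif(1, 0, config$duration_s - dur)
      if (.interval_union_overlap(s - 0.1, s + dur + 0.1, busy) == 0) {
        placed <- TRUE
        break
      }
    }
    if (!placed) next
    idx <- (as.integer(round(s * rate)) + 1):as.integer(round((s + dur) * rate))
    if (is_hum) {
      f0 <- stats::runif(1, 200, 500)
      ramp <- pmin(1, seq_along(idx) / (0.05 * rate),
                   rev(seq_along(idx)) / (0.05 * rate))
      out[idx] <- out[idx] +
        bg_rms * sqrt(2) * sin(2 * pi * f0 * seq_along(idx) / rate) * ramp
    } else {
      out[idx] <- out[idx] + 0.5 * exp(-seq_along(idx) / (0.001 * rate))
    }
    busy <- .merge_intervals(event_list(c(busy$start_s, s),
                                        c(busy$end_s, s + dur),
                                        "busy", require_disjoint = FALSE))
  }
  out
}

#' Generate a synthetic train/test cohort on disk
#'
#' Writes one 16-bit WAV and one gold events CSV per synthetic
#' participant, plus a JSON manifest recording roles, per-recording seeds
#' and the configuration. The test cohort's background can follow a
#' shifted profile (different spectral slope and level) to emulate the
#' train/test domain mismatch of training on one recording setup and
#' testing on another; `test_profile = "matched"` disables the shift.
#'
#' @param n_train,n_test Numbers of training and test participants (>= 1).
#' @param out_dir Output directory (must not already contain files).
#' @param config Base [sim_config()] shared by all recordings.
#' @param seed Cohort seed; per-recording seeds are derived from it.
#' @param test_profile `"shifted"` (default) or `"matched"`.
#' @param test_background Background overrides used when
#'   `test_profile = "shifted"`.
#' @return The manifest, invisibly.
#' @export
generate_cohort <- function(n_train, n_test, out_dir, config = sim_config(),
                            seed = 1L, test_profile = c("shifted", "matched"),
                            test_background = list(exponent = 1.0, level_db = 3)) {
  stopifnot(n_train >= 1, n_test >= 1)
  test_profile <- match.arg(test_profile)
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0) {
    stopf("output directory '%s' already contains files", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ids <- c(sprintf("train%02d", seq_len(n_train)),
           sprintf("test%02d", seq_len(n_test)))
  roles <- rep(c("train", "test"), c(n_train, n_test))
  recs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, i)
    if (roles[i] == "test" && test_profile == "shifted") {
      cfg$background <- test_background
    }
    r <- generate_recording(cfg)
    write_wav(r$signal, file.path(out_dir, paste0(ids[i], ".wav")))
    write_events_csv(r$events, file.path(out_dir, paste0(ids[i], ".csv")))
    recs[[i]] <- list(id = ids[i], role = roles[i], seed = cfg$seed,
                      n_events = nrow(r$events))
  }
  manifest <- list(seed = as.integer(seed), test_profile = test_profile,
                   config = unclass(config),
                   test_background = if (test_profile == "shifted") test_background,
                   recordings = recs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
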