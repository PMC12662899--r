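# WAV reading/writing, resampling, normalization, annotation CSV I/O.

test_that("read_wav decodes PCM, scales by full scale, and downmixes", {
  d <- withr::local_tempdir()

  # 2 s @ 44.1 kHz mono: length and rate bookkeeping
  p1 <- write_pcm16_wav(file.path(d, "mono.wav"),
                        rep(0L, 88200), rate = 44100)
  s1 <- read_wav(p1)
  expect_equal(length(s1$samples), 88200)
  expect_equal(s1$rate, 44100)

  # stereo with identical channels of value 0.5 stays 0.5 after downmix
  half <- as.integer(round(0.5 * 32768))
  p2 <- write_pcm16_wav(file.path(d, "stereo.wav"),
                        rep(half, 2 * 1000), rate = 16000, n_channels = 2)
  s2 <- read_wav(p2)
  expect_equal(length(s2$samples), 1000)
  expect_equal(s2$samples, rep(half / 32768, 1000))

  # integer full scale maps to ~1.0
  p3 <- write_pcm16_wav(file.path(d, "full.wav"), rep(32767L, 500), 16000)
  expect_equal(read_wav(p3)$samples, rep(32767 / 32768, 500))
  expect_true(all(abs(read_wav(p3)$samples - 1) < 1e-4))

  expect_error(read_wav(file.path(d, "absent.wav")), "absent.wav")
})

test_that("write_wav/read_wav round-trips at 16-bit precision", {
  d <- withr::local_tempdir()
  set.seed(11)
  x <- audio_signal(runif(4000, -1, 1), 16000)
  p <- file.path(d, "rt.wav")
  write_wav(x, p)
  y <- read_wav(p)
  expect_equal(y$rate, 16000)
  expect_equal(y$samples, x$samples, tolerance = 2 / 32768)
})

test_that("resample_audio converts rate, length and spectrum correctly", {
  s <- tone(1000, dur_s = 1, rate = 44100)
  r <- resample_audio(s, 16000)
  expect_equal(r$rate, 16000)
  expect_equal(length(r$samples), 16000)

  # spectral peak preserved at 1 kHz within one FFT bin
  spec <- abs(fft(r$samples))[1:8000]
  peak_hz <- (which.max(spec) - 1) * 16000 / 16000
  expect_lte(abs(peak_hz - 1000), 16000 / 16000)

  # identity case: returned unchanged
  s16 <- tone(440, dur_s = 0.5, rate = 16000)
  expect_identical(resample_audio(s16, 16000), s16)

  # second pass at the same rate changes nothing
  expect_identical(resample_audio(r, 16000), r)

  expect_error(resample_audio(s, -1), "positive")
})

test_that("normalize_amplitude scales the peak to 1 and is idempotent", {
  z <- audio_signal(numeric(100), 16000)
  expect_identical(normalize_amplitude(z), z)

  s <- audio_signal(c(-0.2, 0.1, 0.4), 16000)
  n1 <- normalize_amplitude(s)
  expect_equal(n1$samples, c(-0.5, 0.25, 1.0))

  big <- audio_signal(2 * sin(seq(0, 10, length.out = 500)), 8000)
  nb <- normalize_amplitude(big)
  expect_equal(max(abs(nb$samples)), 1)
  expect_equal(normalize_amplitude(nb)$samples, nb$samples)
})

test_that("events CSV round-trips, sorts, and rejects malformed rows", {
  d <- withr::local_tempdir()
  p <- file.path(d, "ev.csv")

  ev <- event_list(c(0.5, 3.0), c(1.1, 3.4), "swallow")
  write_events_csv(ev, p)
  expect_equal(read_events_csv(p), ev)

  # header-only file -> empty list
  writeLines("start_s,end_s,label", p)
  expect_equal(nrow(read_events_csv(p)), 0)

  # unsorted on disk -> sorted in memory
  writeLines(c("start_s,end_s,label",
               "3.000,3.400,swallow",
               "0.500,1.100,swallow"), p)
  expect_equal(read_events_csv(p)$start_s, c(0.5, 3.0))

  # malformed rows are reported with their line number
  writeLines(c("start_s,end_s,label", "1.0,0.5,swallow"), p)
  expect_error(read_events_csv(p), "line 2")
  writeLines(c("start_s,end_s,label", "0.5,1.0,swallow", "-1,2,swallow"), p)
  expect_error(read_events_csv(p), "line 3")
})

test_that("CSV round-trip is the identity at millisecond precision", {
  d <- withr::local_tempdir()
  set.seed(21)
  for (i in 1:5) {
    ev <- random_events(sample(1:8, 1))
    ev$start_s <- round(ev$start_s, 3)
    ev$end_s <- round(ev$end_s, 3)
    p <- file.path(d, sprintf("rt%d.csv", i))
    write_events_csv(ev, p)
    expect_equal(read_events_csv(p), ev)
  }
})
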