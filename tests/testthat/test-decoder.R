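# Overlap-add accumulation, thresholding, event extraction.

test_that("accumulate_confidence overlap-adds on the slot grid", {
  tl <- accumulate_confidence(c(0, 0.48), rbind(rep(1, 6), rep(0, 6)))
  expect_equal(tl$sum, c(1, 1, 1, 1, 1, 1, 0, 0, 0))
  expect_equal(tl$coverage, c(1, 1, 1, 2, 2, 2, 1, 1, 1))

  single <- accumulate_confidence(0.48, seq(0.1, 0.6, by = 0.1))
  expect_equal(single$sum, c(0, 0, 0, seq(0.1, 0.6, by = 0.1)))
  expect_equal(single$coverage, c(0, 0, 0, rep(1, 6)))

  zero <- accumulate_confidence(c(0, 0.48), matrix(0, 2, 6))
  expect_true(all(zero$sum == 0))

  expect_error(accumulate_confidence(0.1, rep(0.5, 6)), "multiples")
})

test_that("accumulate_confidence matches brute-force slot accumulation", {
  set.seed(61)
  for (rep in 1:20) {
    n_frames <- sample(1:15, 1)
    starts <- sort(sample(0:20, n_frames)) * 0.48
    conf <- matrix(runif(n_frames * 6), n_frames)
    tl <- accumulate_confidence(starts, conf)
    n_slots <- length(tl$sum)
    for (j in seq_len(n_slots)) {
      slot_lo <- (j - 1) * 0.16
      s <- 0; k <- 0
      for (i in seq_len(n_frames)) {
        sub <- round((slot_lo - starts[i]) / 0.16) + 1
        if (sub >= 1 && sub <= 6 &&
            abs(starts[i] + (sub - 1) * 0.16 - slot_lo) < 1e-9) {
          s <- s + conf[i, sub]; k <- k + 1
        }
      }
      expect_equal(tl$sum[j], s)
      expect_equal(tl$coverage[j], k)
    }
  }
})

test_that("threshold_mask uses the coverage-normalized mean with ties to 1", {
  tl <- accumulate_confidence(c(0, 0.48), rbind(rep(1, 6), rep(0, 6)))
  expect_equal(threshold_mask(tl, 0.5), c(1, 1, 1, 1, 1, 1, 0, 0, 0))
  expect_equal(threshold_mask(tl, 0.51), c(1, 1, 1, 0, 0, 0, 0, 0, 0))

  zero <- accumulate_confidence(0, rep(0, 6))
  expect_true(all(threshold_mask(zero, 0.5) == 0))

  expect_error(threshold_mask(tl, 0), "between 0 and 1")
  expect_error(threshold_mask(tl, 1), "between 0 and 1")
})

test_that("thresholding is invariant to duplicated frame contributions", {
  set.seed(62)
  starts <- c(0, 0.48, 0.96)
  conf <- matrix(runif(18), 3)
  m1 <- threshold_mask(accumulate_confidence(starts, conf), 0.4)
  m2 <- threshold_mask(accumulate_confidence(rep(starts, 2),
                                             rbind(conf, conf)), 0.4)
  expect_equal(m1, m2)
})

test_that("mask_to_events extracts runs, merges gaps, drops shorts", {
  ev <- mask_to_events(c(0, 1, 1, 0, 0, 1))
  expect_equal(ev$start_s, c(0.16, 0.80))
  expect_equal(ev$end_s, c(0.48, 0.96))

  expect_equal(nrow(mask_to_events(rep(0, 10))), 0)

  merged <- mask_to_events(c(1, 1, 0, 1), merge_gap_s = 0.16)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start_s, 0)
  expect_equal(merged$end_s, 0.64)

  kept <- mask_to_events(c(1, 0, 0, 1, 1), min_duration_s = 0.32)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$start_s, 0.48)

  # boundaries are quantized to the slot grid, events disjoint and sorted
  set.seed(63)
  for (rep in 1:10) {
    mask <- rbinom(40, 1, 0.4)
    ev <- mask_to_events(mask)
    if (nrow(ev) > 0) {
      expect_equal(ev$start_s / 0.16, round(ev$start_s / 0.16))
      expect_equal(ev$end_s / 0.16, round(ev$end_s / 0.16))
      expect_true(!is.unsorted(ev$start_s))
      if (nrow(ev) > 1) expect_true(all(ev$start_s[-1] >= ev$end_s[-nrow(ev)]))
    }
  }
})

test_that("label round-trip recovers event boundaries within one slot", {
  set.seed(64)
  for (rep in 1:20) {
    truth <- random_events(sample(2:6, 1), span_s = 20)
    starts <- seq(0, by = 0.48, length.out = ceiling(20 / 0.48))
    labels <- labels_for_recording(starts, truth)
    tl <- accumulate_confidence(starts, labels)  # oracle confidences
    rec <- mask_to_events(threshold_mask(tl, 0.5))
    expect_equal(nrow(rec), nrow(truth))
    expect_true(all(abs(rec$start_s - truth$start_s) <= 0.16 + 1e-9))
    expect_true(all(abs(rec$end_s - truth$end_s) <= 0.16 + 1e-9))
  }
})
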