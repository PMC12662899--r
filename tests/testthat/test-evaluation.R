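# Event matching, subframe confusion, metric suite.

test_that("match_events applies the inclusive 30% overlap rule", {
  truth <- event_list(0, 1.0, "swallow")

  m <- match_events(truth, event_list(0, 0.30, "swallow"))
  expect_equal(m$truth_verdict, "TP")
  expect_equal(m$predicted_verdict, "TP")

  m2 <- match_events(truth, event_list(0, 0.29, "swallow"))
  expect_equal(m2$truth_verdict, "FN")
  expect_equal(m2$predicted_verdict, "FP")

  m3 <- match_events(truth, event_list(numeric(), numeric(), character()))
  expect_equal(m3$truth_verdict, "FN")
  expect_equal(m3$fn, 1)
  expect_equal(m3$fp, 0)

  # fragments jointly covering 30% count (union rule)
  m4 <- match_events(truth, event_list(c(0, 0.5), c(0.15, 0.65), "swallow",
                                       require_disjoint = FALSE))
  expect_equal(m4$truth_verdict, "TP")
  expect_equal(m4$overlap_frac, 0.30)
})

test_that("adding a prediction never converts a TP truth into an FN", {
  set.seed(71)
  for (rep in 1:10) {
    truth <- random_events(4, span_s = 15)
    pred <- random_events(3, span_s = 15)
    m_before <- match_events(truth, pred)
    extra <- event_list(c(pred$start_s, 0.05), c(pred$end_s, 0.2),
                        "swallow", require_disjoint = FALSE)
    m_after <- match_events(truth, extra)
    expect_true(all(!(m_before$truth_verdict == "TP" &
                        m_after$truth_verdict == "FN")))
  }
})

test_that("subframe_confusion tallies slots", {
  cc <- subframe_confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unclass(cc)[c("tp", "fn", "fp", "tn")],
               list(tp = 1L, fn = 1L, fp = 1L, tn = 1L))

  same <- subframe_confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(same$fp + same$fn, 0)

  allfp <- subframe_confusion(rep(0, 8), rep(1, 8))
  expect_equal(allfp$fp, 8)
  expect_equal(allfp$tp + allfp$fn + allfp$tn, 0)

  expect_error(subframe_confusion(c(1, 0), c(1, 0, 1)), "lengths differ")
})

test_that("metrics_from_counts reproduces hand-derived values", {
  m <- metrics_from_counts(confusion_counts(tp = 10, fn = 0, fp = 0, tn = 10))
  expect_equal(m$accuracy, 1)
  expect_equal(m$swallow$f1, 1)
  expect_equal(m$non_swallow$sensitivity, 1)

  m2 <- metrics_from_counts(confusion_counts(tp = 1, fn = 1, fp = 1, tn = 1))
  for (v in unlist(m2[c("accuracy", "swallow", "non_swallow")])) {
    expect_equal(v, 0.5)
  }

  # zero denominators surface as NA, never 0
  m3 <- metrics_from_counts(confusion_counts(tp = 0, fn = 0, fp = 5, tn = 5))
  expect_true(is.na(m3$swallow$sensitivity))
  expect_true(is.na(m3$swallow$f1))
  expect_equal(m3$non_swallow$sensitivity, 0.5)
})

test_that("metric identities hold and match an independent implementation", {
  oracle <- function(tp, fn, fp, tn) {
    safe <- function(x) ifelse(is.nan(x) | is.infinite(x), NA_real_, x)
    prec1 <- safe(tp / (tp + fp)); rec1 <- safe(tp / (tp + fn))
    prec0 <- safe(tn / (tn + fn)); rec0 <- safe(tn / (tn + fp))
    list(acc = (tp + tn) / (tp + fn + fp + tn),
         ppv1 = prec1, sens1 = rec1,
         f11 = safe(2 / (1 / prec1 + 1 / rec1)),
         ppv0 = prec0, sens0 = rec0,
         f10 = safe(2 / (1 / prec0 + 1 / rec0)))
  }
  set.seed(72)
  for (i in 1:1000) {
    v <- rpois(4, 20)
    m <- metrics_from_counts(confusion_counts(v[1], v[2], v[3], v[4]))
    if (sum(v) == 0) next
    o <- oracle(v[1], v[2], v[3], v[4])
    expect_equal(m$accuracy, o$acc)
    expect_equal(m$swallow$ppv, o$ppv1)
    expect_equal(m$swallow$sensitivity, o$sens1)
    expect_equal(m$swallow$f1, o$f11)
    expect_equal(m$non_swallow$f1, o$f10)
    # class-symmetry identities
    expect_equal(m$swallow$specificity, m$non_swallow$sensitivity)
    expect_equal(m$non_swallow$specificity, m$swallow$sensitivity)
    expect_equal(m$swallow$npv, m$non_swallow$ppv)
    expect_equal(m$non_swallow$npv, m$swallow$ppv)
  }
})

test_that("events_to_mask applies the half-slot occupancy rule", {
  ev <- event_list(0.20, 0.30, "swallow")  # 0.10 s inside slot 2
  expect_equal(events_to_mask(ev, 4), c(0L, 1L, 0L, 0L))
  none <- event_list(numeric(), numeric(), character())
  expect_equal(events_to_mask(none, 3), c(0L, 0L, 0L))
})

test_that("evaluate_events agrees between identical truth and prediction", {
  truth <- event_list(c(1, 5), c(1.6, 5.8), "swallow")
  r <- evaluate_events(truth, truth, duration_s = 10)
  expect_equal(r$event$sensitivity, 1)
  expect_equal(r$event$precision, 1)
  expect_equal(r$subframe$counts$fp, 0)
  expect_equal(r$subframe$counts$fn, 0)
})
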