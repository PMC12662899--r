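# Event-overlap matching, subframe confusion matrices and the clinical
# metric suite (PPV/NPV/specificity/sensitivity/F1 per class + accuracy).
#
# Event matching follows the at-least-30%-overlap rule: a ground-truth
# swallow counts as detected when at least 30% of its duration is covered
# by predicted swallow time (coverage is computed against the union of
# predictions, so fragmented detections jointly covering 30% count).

#' Match predicted events against ground truth
#'
#' Each ground-truth event is a true positive iff the fraction of its
#' duration covered by the union of predicted events is at least
#' `min_overlap_frac` (inclusive), else a false negative. Each predicted
#' event is a true positive iff it overlaps any detected (TP) true event,
#' else a false positive; one prediction may match several true events
#' and vice versa.
#'
#' @param truth Ground-truth event list (sorted, disjoint).
#' @param predicted Predicted event list (sorted).
#' @param min_overlap_frac Minimum covered fraction; default 0.30.
#' @return A list: `truth_verdict` ("TP"/"FN" per true event),
#'   `predicted_verdict` ("TP"/"FP" per predicted event), `overlap_frac`
#'   (covered fraction per true event), and counts `tp`, `fn`, `fp`
#'   (event-level; `tp` counts detected true events).
#' @export
match_events <- function(truth, predicted, min_overlap_frac = 0.30) {
  validate_events(truth)
  validate_events(predicted, require_disjoint = FALSE)
  n_t <- nrow(truth)
  n_p <- nrow(predicted)
  pred_union <- .merge_intervals(predicted)
  frac <- vapply(seq_len(n_t), function(i) {
    dur <- truth$end_s[i] - truth$start_s[i]
    .interval_union_overlap(truth$start_s[i], truth$end_s[i], pred_union) / dur
  }, numeric(1))
  truth_verdict <- ifelse(frac >= min_overlap_frac - 1e-12, "TP", "FN")
  detected <- truth[truth_verdict == "TP", , drop = FALSE]
  predicted_verdict <- vapply(seq_len(n_p), function(j) {
    if (.interval_union_overlap(predicted$start_s[j], predicted$end_s[j],
                                detected) > 0) "TP" else "FP"
  }, character(1))
  list(truth_verdict = truth_verdict,
       predicted_verdict = predicted_verdict,
       overlap_frac = frac,
       tp = sum(truth_verdict == "TP"),
       fn = sum(truth_verdict == "FN"),
       fp = sum(predicted_verdict == "FP"))
}

# union of possibly-overlapping intervals -> disjoint sorted event list
.merge_intervals <- function(events) {
  if (nrow(events) <= 1) return(events)
  ev <- events[order(events$start_s), , drop = FALSE]
  out_s <- ev$start_s[1]; out_e <- ev$end_s[1]
  for (i in 2:nrow(ev)) {
    if (ev$start_s[i] <= out_e[length(out_e)]) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], ev$end_s[i])
    } else {
      out_s <- c(out_s, ev$start_s[i]); out_e <- c(out_e, ev$end_s[i])
    }
  }
  event_list(out_s, out_e, "union")
}

#' Confusion counts container
#'
#' @param tp,fn,fp,tn Non-negative counts; class 1 ("swallow") is positive.
#' @return A list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("confusion counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' Slot-wise confusion counts between two binary masks
#'
#' Both masks live on the same 0.16 s grid; see [events_to_mask()] for
#' rendering an event list onto that grid.
#'
#' @param true_mask,predicted_mask Equal-length 0/1 vectors.
#' @return A `confusion_counts`.
#' @export
subframe_confusion <- function(true_mask, predicted_mask) {
  if (length(true_mask) != length(predicted_mask)) {
    stopf("mask lengths differ (%d vs %d)", length(true_mask),
          length(predicted_mask))
  }
  t1 <- as.integer(true_mask != 0)
  p1 <- as.integer(predicted_mask != 0)
  confusion_counts(tp = sum(t1 == 1 & p1 == 1),
                   fn = sum(t1 == 1 & p1 == 0),
                   fp = sum(t1 == 0 & p1 == 1),
                   tn = sum(t1 == 0 & p1 == 0))
}

#' Render an event list onto the 0.16 s slot grid
#'
#' A slot is 1 when at least half of it (0.08 s) is covered by event time
#' — the same occupancy rule used for training labels, so ground truth
#' and decoder output are comparable on one grid.
#'
#' @param events An event list.
#' @param n_slots Number of slots in the grid.
#' @param slot_s Slot duration (default 0.16 s).
#' @return Integer 0/1 vector of length `n_slots`.
#' @export
events_to_mask <- function(events, n_slots, slot_s = SUBFRAME_S) {
  validate_events(events, require_disjoint = FALSE)
  ev <- .merge_intervals(events)
  vapply(seq_len(n_slots), function(j) {
    a <- (j - 1L) * slot_s
    as.integer(.interval_union_overlap(a, a + slot_s, ev) >=
                 slot_s / 2 - 1e-12)
  }, integer(1))
}

#' Clinical metric suite from confusion counts
#'
#' For the swallow (positive) class: PPV = tp/(tp+fp), NPV = tn/(tn+fn),
#' sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), F1 = harmonic mean
#' of PPV and sensitivity; the non-swallow class swaps the roles of
#' positives and negatives. Accuracy = (tp+tn)/total. Any metric with a
#' zero denominator is `NA`, never 0.
#'
#' @param counts A `confusion_counts` (or list with tp/fn/fp/tn).
#' @return A list of class `metrics_report`: `accuracy`, and per class
#'   (`swallow`, `non_swallow`) `ppv`, `npv`, `specificity`,
#'   `sensitivity`, `f1`.
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts$tp; fn <- counts$fn; fp <- counts$fp; tn <- counts$tn
  total <- tp + fn + fp + tn
  if (total == 0) stopf("confusion counts are all zero")
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  cls <- function(tp, fn, fp, tn) {
    ppv <- div(tp, tp + fp)
    sens <- div(tp, tp + fn)
    f1 <- if (is.na(ppv) || is.na(sens) || ppv + sens == 0) NA_real_ else {
      2 * ppv * sens / (ppv + sens)
    }
    list(ppv = ppv, npv = div(tn, tn + fn), specificity = div(tn, tn + fp),
         sensitivity = sens, f1 = f1)
  }
  structure(list(accuracy = div(tp + tn, total),
                 swallow = cls(tp, fn, fp, tn),
                 non_swallow = cls(tn, fp, fn, tp),
                 counts = list(tp = tp, fn = fn, fp = fp, tn = tn)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "  NA", sprintf("%.3f", v))
  cat(sprintf("accuracy: %s  (tp %d, fn %d, fp %d, tn %d)\n",
              fmt(x$accuracy), x$counts$tp, x$counts$fn, x$counts$fp,
              x$counts$tn))
  cat("class         PPV    NPV    Spec   Sens   F1\n")
  for (nm in c("non_swallow", "swallow")) {
    m <- x[[nm]]
    cat(sprintf("%-12s %s  %s  %s  %s  %s\n", nm, fmt(m$ppv), fmt(m$npv),
                fmt(m$specificity), fmt(m$sensitivity), fmt(m$f1)))
  }
  invisible(x)
}

#' Evaluate predicted events against ground truth on one recording
#'
#' Computes both evaluation granularities: event-level verdicts under the
#' 30% overlap rule and the slot-wise subframe confusion matrix with its
#' metric suite.
#'
#' @param truth,predicted Event lists.
#' @param duration_s Recording duration (sets the slot-grid length).
#' @param min_overlap_frac Event-match threshold (default 0.30).
#' @return A list: `event` (match_events output plus sensitivity and
#'   precision), `subframe` (counts + metrics_report).
#' @export
evaluate_events <- function(truth, predicted, duration_s,
                            min_overlap_frac = 0.30) {
  m <- match_events(truth, predicted, min_overlap_frac)
  n_slots <- as.integer(ceiling(duration_s / SUBFRAME_S))
  cc <- subframe_confusion(events_to_mask(truth, n_slots),
                           events_to_mask(predicted, n_slots))
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(event = c(m, list(sensitivity = div(m$tp, m$tp + m$fn),
                         precision = div(sum(m$predicted_verdict == "TP"),
                                         length(m$predicted_verdict)))),
       subframe = list(counts = cc, metrics = metrics_from_counts(cc)))
}
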