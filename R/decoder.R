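# Overlap-add decoding of per-frame subframe confidences.
#
# Each frame contributes six confidences on the absolute 0.16 s slot grid.
# With the 0.48 s hop, consecutive frames overlap by three slots, so
# interior slots are covered twice. Contributions are summed per slot
# together with a coverage count; thresholding uses the coverage-
# normalized mean so one threshold is meaningful at recording edges
# (coverage 1) and in the interior (coverage 2) alike.

#' Overlap-add subframe confidences onto a recording timeline
#'
#' @param frame_starts_s Frame start times in seconds; each must sit on
#'   the 0.16 s slot grid (the 0.48 s framing grid satisfies this).
#' @param confidences Matrix with one row of six subframe confidences per
#'   frame (a single frame may be given as a vector).
#' @return A list of class `confidence_timeline`: `sum` (per-slot summed
#'   confidence), `coverage` (frames overlapping each slot), `slot_s`.
#' @export
accumulate_confidence <- function(frame_starts_s, confidences) {
  if (is.null(dim(confidences))) confidences <- matrix(confidences, nrow = 1)
  confidences <- as.matrix(confidences)
  if (length(frame_starts_s) != nrow(confidences)) {
    stopf("need one confidence vector per frame start")
  }
  if (ncol(confidences) != N_SUBFRAMES) {
    stopf("confidence vectors must have %d entries", N_SUBFRAMES)
  }
  slot0 <- frame_starts_s / SUBFRAME_S
  if (any(abs(slot0 - round(slot0)) > 1e-9)) {
    stopf("frame starts must be multiples of the %.2f s slot duration", SUBFRAME_S)
  }
  slot0 <- as.integer(round(slot0))
  n_slots <- max(slot0) + N_SUBFRAMES
  s <- numeric(n_slots)
  k <- integer(n_slots)
  for (i in seq_along(slot0)) {
    j <- slot0[i] + seq_len(N_SUBFRAMES)
    s[j] <- s[j] + confidences[i, ]
    k[j] <- k[j] + 1L
  }
  structure(list(sum = s, coverage = k, slot_s = SUBFRAME_S),
            class = "confidence_timeline")
}

#' @export
print.confidence_timeline <- function(x, ...) {
  cat(sprintf("<confidence_timeline: %d slots of %.2f s>\n",
              length(x$sum), x$slot_s))
  invisible(x)
}

#' Threshold a confidence timeline into a binary slot mask
#'
#' A slot is active when its coverage-normalized mean confidence is at
#' least `tau` (ties go to 1). Slots never covered by a frame are 0.
#'
#' @param timeline A `confidence_timeline`.
#' @param tau Decision threshold in (0, 1); default 0.5.
#' @return Integer 0/1 vector, one entry per slot.
#' @export
threshold_mask <- function(timeline, tau = 0.5) {
  stopifnot(inherits(timeline, "confidence_timeline"))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1) {
    stopf("tau must lie strictly between 0 and 1")
  }
  mean_conf <- ifelse(timeline$coverage > 0, timeline$sum / pmax(timeline$coverage, 1L), 0)
  as.integer(mean_conf >= tau)
}

#' Convert a binary slot mask into time-stamped events
#'
#' Maximal runs of 1s become events `[first_slot * 0.16, (last_slot + 1) *
#' 0.16)`. Runs separated by gaps of at most `merge_gap_s` are merged
#' first; events shorter than `min_duration_s` are then dropped. All
#' boundaries are multiples of the slot duration, the decoder's temporal
#' resolution. Both postprocessing knobs default to 0 (raw segments).
#'
#' @param mask Integer/logical 0/1 vector on the 0.16 s grid.
#' @param slot_s Slot duration in seconds (default 0.16).
#' @param min_duration_s Drop events shorter than this.
#' @param merge_gap_s Merge runs separated by gaps of at most this.
#' @param label Label for the produced events.
#' @return An event list data.frame.
#' @export
mask_to_events <- function(mask, slot_s = SUBFRAME_S, min_duration_s = 0,
                           merge_gap_s = 0, label = "swallow") {
  mask <- as.integer(mask != 0)
  if (length(mask) == 0 || !any(mask == 1)) {
    return(event_list(numeric(), numeric(), character()))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values == 1], end = ends[r$values == 1])
  if (merge_gap_s > 0 && nrow(runs) > 1) {
    merged <- runs[1, ]
    for (i in 2:nrow(runs)) {
      gap_s <- (runs$start[i] - merged$end[nrow(merged)] - 1L) * slot_s
      if (gap_s <= merge_gap_s + 1e-12) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  start_s <- (runs$start - 1L) * slot_s
  end_s <- runs$end * slot_s
  keep <- (end_s - start_s) >= min_duration_s - 1e-12
  event_list(start_s[keep], end_s[keep], label)
}

#' Segment a recording into predicted swallow events
#'
#' End-to-end inference: features -> head -> overlap-add -> threshold ->
#' events. The backend must match the one recorded in the model artifact.
#'
#' @param signal An [audio_signal()] at 16 kHz.
#' @param head A `trained_head`.
#' @param backend An `embedding_backend`; must match `head$backend`.
#' @param tau Decision threshold (default 0.5).
#' @param min_duration_s,merge_gap_s Postprocessing, see [mask_to_events()].
#' @return A list: `events` (event list), `timeline`, `mask`.
#' @export
segment_recording <- function(signal, head, backend, tau = 0.5,
                              min_duration_s = 0, merge_gap_s = 0) {
  stopifnot(inherits(head, "trained_head"), inherits(backend, "embedding_backend"))
  if (!identical(backend$name, head$backend$name) ||
      backend$dim != head$backend$dim) {
    stopf("backend '%s' (dim %d) does not match the model's backend '%s' (dim %d)",
          backend$name, backend$dim, head$backend$name, head$backend$dim)
  }
  ft <- featurize_recording(signal, backend)
  conf <- predict_head(head, ft$features)
  timeline <- accumulate_confidence(ft$starts_s, conf)
  mask <- threshold_mask(timeline, tau)
  list(events = mask_to_events(mask, min_duration_s = min_duration_s,
                               merge_gap_s = merge_gap_s),
       timeline = timeline, mask = mask)
}
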