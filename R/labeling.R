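# Ground-truth subframe labels.
#
# Each 0.96 s frame is subdivided into six 0.16 s subframes; subframe i of
# a frame starting at t covers [t + 0.16 i, t + 0.16 (i + 1)). A subframe
# is labelled 1 when at least half of it (0.08 s) is covered by swallow
# time. Labels are computed in absolute recording time, so a time slot
# shared by two overlapping frames always receives the same label.

SUBFRAME_OVERLAP_MIN_S <- SUBFRAME_S / 2  # 0.08 s: 50% occupancy rule

#' Subframe labels for one frame
#'
#' Subframe i (0-based) is labelled 1 iff the total overlap between
#' `[start + 0.16 i, start + 0.16 (i + 1))` and the union of the swallow
#' intervals is at least 0.08 s (half the subframe).
#'
#' @param frame_start_s Frame start time in seconds.
#' @param events Ground-truth event list (sorted, disjoint).
#' @return Integer vector of six 0/1 labels.
#' @export
subframe_labels <- function(frame_start_s, events) {
  validate_events(events)
  sub_start <- frame_start_s + (seq_len(N_SUBFRAMES) - 1L) * SUBFRAME_S
  sub_end <- sub_start + SUBFRAME_S
  overlap <- vapply(seq_len(N_SUBFRAMES), function(i) {
    .interval_union_overlap(sub_start[i], sub_end[i], events)
  }, numeric(1))
  as.integer(overlap >= SUBFRAME_OVERLAP_MIN_S - 1e-12)
}

# total length of [a, b) covered by the (disjoint) intervals in `events`
.interval_union_overlap <- function(a, b, events) {
  if (nrow(events) == 0) return(0)
  sum(pmax(0, pmin(b, events$end_s) - pmax(a, events$start_s)))
}

#' Subframe labels for every frame of a recording
#'
#' @param frames A `frame_set` from [frame_signal()] (only `starts_s` is
#'   used), or a numeric vector of frame start times.
#' @param events Ground-truth event list.
#' @return Integer matrix, one row of six labels per frame.
#' @export
labels_for_recording <- function(frames, events) {
  starts <- if (inherits(frames, "frame_set")) frames$starts_s else as.numeric(frames)
  t(vapply(starts, subframe_labels, integer(N_SUBFRAMES), events = events))
}
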