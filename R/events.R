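#' Construct an event list
#'
#' Event lists are plain data frames with columns `start_s`, `end_s` and
#' `label`, describing half-open time intervals `[start_s, end_s)` in
#' seconds. They are the common currency for ground-truth and predicted
#' swallow annotations. The constructor sorts by start time and validates.
#'
#' @param start_s Numeric vector of interval starts (seconds, >= 0).
#' @param end_s Numeric vector of interval ends (seconds, > start).
#' @param label Character label per interval; default `"swallow"`.
#' @param require_disjoint Require pairwise-disjoint intervals (the
#'   ground-truth contract). Default `TRUE`.
#' @return A data.frame with columns `start_s`, `end_s`, `label`, sorted by
#'   `start_s`.
#' @export
event_list <- function(start_s = numeric(), end_s = numeric(),
                       label = "swallow", require_disjoint = TRUE) {
  n <- length(start_s)
  if (length(end_s) != n) stopf("start_s and end_s lengths differ")
  label <- rep_len(as.character(label), n)
  ev <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   label = label, stringsAsFactors = FALSE)
  ev <- ev[order(ev$start_s, ev$end_s), , drop = FALSE]
  rownames(ev) <- NULL
  validate_events(ev, require_disjoint = require_disjoint)
  ev
}

#' Validate an event list
#'
#' @param events A data.frame with `start_s`, `end_s`, `label` columns.
#' @param require_disjoint Also check pairwise disjointness (ground truth
#'   must be disjoint; predictions from the decoder always are).
#' @return `events`, invisibly; errors describe the first violation.
#' @export
validate_events <- function(events, require_disjoint = TRUE) {
  if (!is.data.frame(events) ||
      !all(c("start_s", "end_s", "label") %in% names(events))) {
    stopf("an event list needs columns start_s, end_s, label")
  }
  if (nrow(events) == 0) return(invisible(events))
  if (any(events$start_s < 0)) stopf("event start times must be >= 0")
  if (any(events$end_s <= events$start_s)) {
    stopf("event end times must exceed start times")
  }
  if (is.unsorted(events$start_s)) stopf("event list must be sorted by start_s")
  if (require_disjoint && nrow(events) > 1) {
    if (any(events$start_s[-1] < events$end_s[-nrow(events)])) {
      stopf("event intervals must be pairwise disjoint")
    }
  }
  invisible(events)
}

#' Read swallow annotations from CSV
#'
#' Expects a header `start_s,end_s,label` with times in seconds. Rows are
#' sorted by start time on read. Malformed rows are reported by line number.
#'
#' @param path CSV file path.
#' @param require_disjoint Passed to [validate_events()].
#' @return An event list data.frame.
#' @export
read_events_csv <- function(path, require_disjoint = TRUE) {
  if (!file.exists(path)) stopf("events CSV not found: '%s'", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("start_s", "end_s", "label") %in% names(df))) {
    stopf("'%s': header must contain start_s,end_s,label", path)
  }
  if (nrow(df) > 0) {
    start <- suppressWarnings(as.numeric(df$start_s))
    end <- suppressWarnings(as.numeric(df$end_s))
    bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
    if (length(bad) > 0) {
      stopf("'%s': malformed event on line %d (need 0 <= start_s < end_s)",
            path, bad[1] + 1L)  # +1 for the header line
    }
    df$start_s <- start
    df$end_s <- end
  }
  event_list(df$start_s, df$end_s, as.character(df$label),
             require_disjoint = require_disjoint)
}

#' Write swallow annotations to CSV
#'
#' Times are written with millisecond precision; a write/read round trip
#' reproduces the event list exactly at that precision.
#'
#' @param events An event list data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  validate_events(events, require_disjoint = FALSE)
  out <- data.frame(start_s = sprintf("%.3f", events$start_s),
                    end_s = sprintf("%.3f", events$end_s),
                    label = events$label)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
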