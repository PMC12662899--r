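# Cohort-level wrappers: featurize a generated (or recorded) cohort,
# train the head with a participant-disjoint split, and evaluate
# segmentations on the test cohort.

#' Build a labelled dataset from a cohort directory
#'
#' Expects `<id>.wav` / `<id>.csv` pairs as written by [generate_cohort()]
#' (or hand-annotated recordings in the same layout). Each recording is
#' resampled to 16 kHz if needed, peak-normalized, featurized under
#' `backend`, and labelled from its gold events.
#'
#' @param dir Cohort directory.
#' @param backend An [embedding_backend()].
#' @param role Which manifest role to load (`"train"` or `"test"`);
#'   ignored when no manifest is present (all pairs are loaded).
#' @return A `labelled_dataset`; attribute `recordings` holds per-id
#'   signals, events and frame starts for downstream decoding.
#' @export
load_cohort_dataset <- function(dir, backend, role = "train") {
  ids <- .cohort_ids(dir, role)
  if (length(ids) == 0) stopf("no '%s' recordings found in '%s'", role, dir)
  parts <- vector("list", length(ids))
  recordings <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sig <- read_wav(file.path(dir, paste0(ids[i], ".wav")))
    if (sig$rate != 16000) sig <- resample_audio(sig, 16000)
    sig <- normalize_amplitude(sig)
    events <- read_events_csv(file.path(dir, paste0(ids[i], ".csv")))
    ft <- featurize_recording(sig, backend)
    labels <- labels_for_recording(ft$starts_s, events)
    parts[[i]] <- labelled_dataset(ft$features, labels, ids[i])
    recordings[[i]] <- list(id = ids[i], signal = sig, events = events,
                            starts_s = ft$starts_s, features = ft$features)
  }
  ds <- bind_datasets(parts)
  attr(ds, "recordings") <- recordings
  ds
}

.cohort_ids <- function(dir, role) {
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    man$recordings$id[man$recordings$role == role]
  } else {
    sub("\\.wav$", "", list.files(dir, pattern = "\\.wav$"))
  }
}

#' Train the head on a cohort directory
#'
#' Featurizes the training recordings, splits them 80/20 by participant,
#' and trains the prediction head.
#'
#' @param dir Cohort directory.
#' @param backend An [embedding_backend()].
#' @param config A [head_config()]; its `input_dim` must equal
#'   `backend$dim + 1`.
#' @param train_fraction Participant fraction for training (default 0.8).
#' @param verbose Print per-epoch losses.
#' @return A list: `head` (trained_head), `split` (participant ids per
#'   side), `dataset`.
#' @export
train_cohort <- function(dir, backend = mel_stats_backend(),
                         config = head_config(input_dim = backend$dim + 1L),
                         train_fraction = 0.8, verbose = FALSE) {
  if (config$input_dim != backend$dim + 1L) {
    stopf("config input_dim %d must be backend dim + 1 = %d",
          config$input_dim, backend$dim + 1L)
  }
  ds <- load_cohort_dataset(dir, backend, role = "train")
  parts <- split_by_participant(ds, train_fraction, seed = config$seed)
  head <- train_head(config, parts$train, parts$validation,
                     backend_name = backend$name, backend_dim = backend$dim,
                     verbose = verbose)
  list(head = head,
       split = list(train = unique(parts$train$participant),
                    validation = unique(parts$validation$participant)),
       dataset = ds)
}

#' Segment and score every test recording of a cohort
#'
#' Runs the decoder on each test recording and aggregates event-level
#' verdicts (30% overlap rule) and subframe confusion counts across
#' recordings.
#'
#' @param dir Cohort directory.
#' @param head A `trained_head`.
#' @param backend The matching [embedding_backend()].
#' @param tau Decision threshold.
#' @param min_overlap_frac Event-match threshold (default 0.30).
#' @param min_duration_s,merge_gap_s Decoder postprocessing knobs.
#' @return A list: `event` (aggregated tp/fn/fp, sensitivity, precision),
#'   `subframe` (aggregated counts + metrics), `per_recording`.
#' @export
evaluate_cohort <- function(dir, head, backend, tau = 0.5,
                            min_overlap_frac = 0.30, min_duration_s = 0,
                            merge_gap_s = 0) {
  ids <- .cohort_ids(dir, "test")
  if (length(ids) == 0) stopf("no test recordings found in '%s'", dir)
  tp <- fn <- fp <- 0L
  n_pred_tp <- n_pred <- 0L
  cc <- c(tp = 0L, fn = 0L, fp = 0L, tn = 0L)
  per <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sig <- read_wav(file.path(dir, paste0(ids[i], ".wav")))
    if (sig$rate != 16000) sig <- resample_audio(sig, 16000)
    sig <- normalize_amplitude(sig)
    truth <- read_events_csv(file.path(dir, paste0(ids[i], ".csv")))
    seg <- segment_recording(sig, head, backend, tau = tau,
                             min_duration_s = min_duration_s,
                             merge_gap_s = merge_gap_s)
    ev <- evaluate_events(truth, seg$events, duration(sig), min_overlap_frac)
    tp <- tp + ev$event$tp; fn <- fn + ev$event$fn; fp <- fp + ev$event$fp
    n_pred_tp <- n_pred_tp + sum(ev$event$predicted_verdict == "TP")
    n_pred <- n_pred + length(ev$event$predicted_verdict)
    sc <- ev$subframe$counts
    cc <- cc + c(tp = sc$tp, fn = sc$fn, fp = sc$fp, tn = sc$tn)
    per[[i]] <- list(id = ids[i], truth = truth, predicted = seg$events,
                     event = ev$event)
  }
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(event = list(tp = tp, fn = fn, fp = fp,
                    sensitivity = div(tp, tp + fn),
                    precision = div(n_pred_tp, n_pred)),
       subframe = list(counts = confusion_counts(cc["tp"], cc["fn"],
                                                 cc["fp"], cc["tn"]),
                       metrics = metrics_from_counts(as.list(cc))),
       per_recording = per)
}
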