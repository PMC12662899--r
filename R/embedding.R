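# Pluggable frame-embedding backends.
#
# A backend maps one 96 x 64 log-Mel patch to a fixed-length vector. The
# downstream head only sees (embedding, zcr) feature vectors, so any
# backend honouring the contract (deterministic, constant dim) slots in
# unchanged. Two ship:
#   * "mel-stats": deterministic and dependency-free. Per-mel-band mean
#     over each of six 16-step temporal blocks (6 x 64, aligned with the
#     0.16 s subframes so temporal position survives the summary) plus
#     per-band sd, min and max over all 96 steps (3 x 64), projected to
#     1024 dims by a fixed seeded random linear map, so model artifacts
#     keep the 1024-dim shape of pretrained audio embeddings. Purely
#     global statistics would be permutation-invariant over time and the
#     head could never assign a swallow to a subframe.
#   * "yamnet": adapter slot for the published pretrained audio
#     classification network's 1024-dim penultimate embeddings; it needs
#     an external model download and a deep-learning runtime, so
#     constructing it here raises an informative error.

MEL_STATS_PROJECTION_SEED <- 180451L  # fixed constant: artifacts reproduce across machines

#' Construct an embedding backend
#'
#' @param name Backend identifier.
#' @param dim Embedding length (positive integer, constant for the
#'   backend's lifetime).
#' @param transform Function mapping a 96 x 64 log-Mel patch to a numeric
#'   vector of length `dim`.
#' @return An object of class `embedding_backend`.
#' @export
embedding_backend <- function(name, dim, transform) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(dim), length(dim) == 1L, dim >= 1,
            is.function(transform))
  structure(list(name = name, dim = as.integer(dim), transform = transform),
            class = "embedding_backend")
}

#' @export
print.embedding_backend <- function(x, ...) {
  cat(sprintf("<embedding_backend '%s', dim %d>\n", x$name, x$dim))
  invisible(x)
}

#' The deterministic mel-statistics fallback backend
#'
#' Summarises each log-Mel patch as per-band block means over six 16-step
#' temporal blocks (aligned with the six 0.16 s subframes, so where in
#' the frame energy occurs is preserved) plus per-band standard
#' deviation, min and max over all 96 steps — 9 x 64 = 576 values — and
#' applies a fixed seeded random projection to `dim` dimensions. Fully
#' offline and deterministic; the default backend for training and tests.
#'
#' @param dim Embedding length; default 1024 to match pretrained audio
#'   embeddings so configs and artifacts are backend-agnostic.
#' @return An `embedding_backend`.
#' @export
mel_stats_backend <- function(dim = 1024L) {
  proj <- .mel_stats_projection(as.integer(dim))
  embedding_backend("mel-stats", dim, function(patch) {
    as.numeric(proj %*% .mel_patch_stats(patch))
  })
}

MEL_STATS_N <- (6L + 3L) * N_MEL  # 6 block means + sd/min/max per band

.mel_patch_stats <- function(patch) {
  block <- rep(seq_len(6L), each = nrow(patch) / 6L)
  block_means <- vapply(seq_len(6L), function(b) {
    colMeans(patch[block == b, , drop = FALSE])
  }, numeric(ncol(patch)))
  c(as.numeric(block_means),
    apply(patch, 2, stats::sd),
    apply(patch, 2, min),
    apply(patch, 2, max))
}

.proj_env <- new.env(parent = emptyenv())
.mel_stats_projection <- function(dim) {
  key <- as.character(dim)
  if (is.null(.proj_env[[key]])) {
    .proj_env[[key]] <- with_local_seed(MEL_STATS_PROJECTION_SEED, {
      matrix(stats::rnorm(dim * MEL_STATS_N), nrow = dim) / sqrt(MEL_STATS_N)
    })
  }
  .proj_env[[key]]
}

#' The pretrained-network adapter backend
#'
#' Placeholder constructor for the published pretrained audio
#' classification network's penultimate-layer embeddings. Loading it
#' requires a deep-learning runtime and a model download, neither bundled
#' here, so this always fails with a message naming the backend; use
#' [mel_stats_backend()] for offline work, or register a custom
#' [embedding_backend()] wrapping your own model.
#'
#' @export
yamnet_backend <- function() {
  stopf(paste("backend 'yamnet' is unavailable: it requires the pretrained",
              "network weights and a deep-learning runtime; use the",
              "'mel-stats' backend or supply a custom embedding_backend()"))
}

#' Resolve a backend by name
#' @param name `"mel-stats"` or `"yamnet"`.
#' @param dim Embedding dimension for `"mel-stats"`.
#' @return An `embedding_backend`.
#' @export
get_backend <- function(name, dim = 1024L) {
  switch(name,
         "mel-stats" = mel_stats_backend(dim),
         "yamnet" = yamnet_backend(),
         stopf("unknown backend '%s'", name))
}

#' Embed a log-Mel patch
#'
#' @param backend An `embedding_backend`.
#' @param patch A 96 x 64 log-Mel patch.
#' @return Numeric vector of length `backend$dim`.
#' @export
embed_patch <- function(backend, patch) {
  stopifnot(inherits(backend, "embedding_backend"))
  if (!is.matrix(patch) || !all(dim(patch) == c(N_STFT_STEPS, N_MEL))) {
    stopf("patch must be a %d x %d matrix", N_STFT_STEPS, N_MEL)
  }
  v <- backend$transform(patch)
  if (length(v) != backend$dim || any(!is.finite(v))) {
    stopf("backend '%s' broke its contract (dim %d, finite values)",
          backend$name, backend$dim)
  }
  v
}

#' Concatenate an embedding with the frame zero-crossing rate
#'
#' The ZCR scalar is appended to the embedding (not to the log-Mel input),
#' giving the feature vector the prediction head consumes.
#'
#' @param embedding Numeric embedding vector.
#' @param zcr Zero-crossing rate in \[0, 1\].
#' @return Numeric vector of length `length(embedding) + 1`.
#' @export
concat_features <- function(embedding, zcr) {
  if (!is.numeric(zcr) || length(zcr) != 1L || zcr < 0 || zcr > 1) {
    stopf("zcr must be a single value in [0, 1]")
  }
  c(embedding, zcr)
}

#' Feature matrix for a whole recording
#'
#' Frames the signal, embeds every frame and appends its ZCR: one row per
#' frame, `backend$dim + 1` columns. By default each mel band's
#' recording-level mean is subtracted from the log-Mel patches before
#' embedding (channel mean normalization, the standard robustness step in
#' sound-event detection): it removes the recording's background spectral
#' colour and level, so a model trained under one background profile
#' transfers to recordings made under another.
#'
#' @param signal An [audio_signal()] at 16 kHz.
#' @param backend An `embedding_backend`.
#' @param channel_norm Subtract per-band recording means before embedding
#'   (default `TRUE`).
#' @return A list: `features` (matrix), `starts_s` (frame start times).
#' @export
featurize_recording <- function(signal, backend, channel_norm = TRUE) {
  ff <- frame_features(signal)
  patches <- ff$patches
  if (channel_norm) {
    band_mean <- Reduce(`+`, lapply(patches, colMeans)) / length(patches)
    patches <- lapply(patches, function(p) sweep(p, 2, band_mean))
  }
  emb <- t(vapply(patches, function(p) embed_patch(backend, p),
                  numeric(backend$dim)))
  list(features = cbind(emb, ff$zcr, deparse.level = 0),
       starts_s = ff$starts_s)
}
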