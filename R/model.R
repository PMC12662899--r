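# The fully-connected prediction head and its training loop.
#
# Architecture: input (embedding dim + 1) -> 1024 -> 1024 -> 512 -> 6,
# ReLU in the hidden layers and sigmoid at the output. Trained with Adam
# on mean squared error against the six binary subframe labels, with L2
# regularisation on the first two hidden layers' weights only, mini-batch
# size 32, at most 100 epochs. Training data are re-balanced (equal counts
# of swallow and non-swallow frames by undersampling) and re-shuffled
# before every epoch. The epoch with the lowest validation loss provides
# the final weights; early stopping (patience 10) is on by default.
# All training runs in base R matrix code on BLAS.

#' Prediction head configuration
#'
#' @param input_dim Feature length: embedding dim + 1 for the ZCR scalar.
#' @param hidden Hidden layer sizes; default `c(1024, 1024, 512)`.
#' @param output_dim Output units; default 6, one per 0.16 s subframe.
#' @param l2 L2 coefficient on the first two hidden layers' weights.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience in epochs (`Inf` to disable).
#' @param seed Integer seed controlling initialization and epoch shuffles.
#' @return A list of class `head_config`.
#' @export
head_config <- function(input_dim = 1025L, hidden = c(1024L, 1024L, 512L),
                        output_dim = 6L, l2 = 1e-4, learning_rate = 1e-3,
                        batch_size = 32L, max_epochs = 100L, patience = 10L,
                        seed = 1L) {
  stopifnot(input_dim >= 1, length(hidden) >= 1, output_dim >= 1,
            l2 >= 0, learning_rate > 0, batch_size >= 1, max_epochs >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 output_dim = as.integer(output_dim),
                 l2 = l2, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = patience, seed = as.integer(seed)),
            class = "head_config")
}

#' Bundle feature rows, labels and participant ids into a dataset
#'
#' @param features Numeric matrix, one feature vector per row.
#' @param labels Integer matrix of 0/1 subframe labels, one row per example.
#' @param participant Participant id per example (recycled if length 1).
#' @return A list of class `labelled_dataset`.
#' @export
labelled_dataset <- function(features, labels, participant) {
  features <- as.matrix(features)
  labels <- as.matrix(labels)
  if (nrow(features) != nrow(labels)) stopf("features/labels row mismatch")
  participant <- rep_len(as.character(participant), nrow(features))
  structure(list(features = features, labels = labels,
                 participant = participant),
            class = "labelled_dataset")
}

#' Concatenate labelled datasets
#' @param ... `labelled_dataset` objects.
#' @return A single `labelled_dataset`.
#' @export
bind_datasets <- function(...) {
  ds <- list(...)
  if (length(ds) == 1 && is.list(ds[[1]]) && !inherits(ds[[1]], "labelled_dataset")) {
    ds <- ds[[1]]
  }
  labelled_dataset(do.call(rbind, lapply(ds, `[[`, "features")),
                   do.call(rbind, lapply(ds, `[[`, "labels")),
                   unlist(lapply(ds, `[[`, "participant")))
}

#' Split a dataset by participant
#'
#' Participants (never individual examples) are partitioned into training
#' and validation groups, so no participant contributes examples to both:
#' the structural guarantee against patient leakage. `round(0.8 * P)`
#' participants (at least 1, at most P - 1) go to training.
#'
#' @param dataset A `labelled_dataset` with >= 2 distinct participants.
#' @param train_fraction Fraction of participants assigned to training.
#' @param seed Integer seed for the random assignment.
#' @return A list with elements `train` and `validation`.
#' @export
split_by_participant <- function(dataset, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(dataset, "labelled_dataset"))
  ids <- sort(unique(dataset$participant))
  if (length(ids) < 2) stopf("need at least 2 distinct participants to split")
  n_train <- min(max(round(train_fraction * length(ids)), 1L), length(ids) - 1L)
  train_ids <- with_local_seed(seed, sample(ids, n_train))
  take <- function(keep) {
    sel <- dataset$participant %in% keep
    labelled_dataset(dataset$features[sel, , drop = FALSE],
                     dataset$labels[sel, , drop = FALSE],
                     dataset$participant[sel])
  }
  list(train = take(train_ids), validation = take(setdiff(ids, train_ids)))
}

#' Balance swallow/non-swallow frames and shuffle
#'
#' Examples whose label vector contains any 1 ("swallow frames") and
#' all-zero examples are equalised by randomly undersampling the majority
#' group without replacement; the retained examples are returned in random
#' order. Called before every training epoch with an epoch-specific seed.
#'
#' @param dataset A `labelled_dataset`.
#' @param epoch_seed Integer seed; identical seeds give identical orderings.
#' @return Integer vector of example indices into `dataset`.
#' @export
balance_and_shuffle <- function(dataset, epoch_seed) {
  stopifnot(inherits(dataset, "labelled_dataset"))
  pos <- which(rowSums(dataset$labels) > 0)
  neg <- which(rowSums(dataset$labels) == 0)
  if (length(pos) == 0 || length(neg) == 0) {
    stopf("degenerate dataset: need both swallow and non-swallow frames to balance")
  }
  k <- min(length(pos), length(neg))
  with_local_seed(epoch_seed, {
    keep <- c(if (length(pos) > k) sample(pos, k) else pos,
              if (length(neg) > k) sample(neg, k) else neg)
    sample(keep)
  })
}

# ---- network internals -----------------------------------------------------

# He (fan-in) initialization for the ReLU layers; the sigmoid output layer
# starts near zero so initial predictions sit at 0.5, where the MSE+sigmoid
# gradient is healthy (large random output weights saturate the sigmoid and
# stall training).
.init_weights <- function(config) {
  dims <- c(config$input_dim, config$hidden, config$output_dim)
  L <- length(dims) - 1L
  with_local_seed(config$seed, {
    lapply(seq_len(L), function(l) {
      fan_in <- dims[l]
      sd_l <- if (l == L) 0.01 else sqrt(2 / fan_in)
      list(W = matrix(stats::rnorm(fan_in * dims[l + 1L], sd = sd_l),
                      nrow = fan_in),
           b = numeric(dims[l + 1L]))
    })
  })
}

# per-feature standardization fitted on the (unbalanced) training set;
# stored in the artifact and applied at prediction time
.fit_scaler <- function(X) {
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sg[!is.finite(sg) | sg < 1e-8] <- 1
  list(mean = mu, sd = sg)
}

.apply_scaler <- function(X, scaler) {
  if (is.null(scaler)) return(X)
  sweep(sweep(X, 2, scaler$mean, `-`), 2, scaler$sd, `/`)
}

.forward <- function(weights, X, keep_cache = FALSE) {
  L <- length(weights)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L - 1L)) {
    Z <- acts[[l]] %*% weights[[l]]$W
    Z <- sweep(Z, 2, weights[[l]]$b, `+`)
    acts[[l + 1L]] <- Z * (Z > 0)  # ReLU
  }
  Z <- acts[[L]] %*% weights[[L]]$W
  Z <- sweep(Z, 2, weights[[L]]$b, `+`)
  out <- 1 / (1 + exp(-Z))  # sigmoid
  if (keep_cache) list(out = out, acts = acts) else out
}

# gradient of mean((out - Y)^2) over all batch x output entries, plus
# L2 (coefficient config$l2) on the first two hidden layers' weights
.backward <- function(weights, cache, Y, config) {
  out <- cache$out; acts <- cache$acts
  L <- length(weights)
  n <- nrow(Y)
  grads <- vector("list", L)
  delta <- (2 / (n * ncol(Y))) * (out - Y) * out * (1 - out)  # dMSE * dsigmoid
  for (l in seq(L, 1L)) {
    gW <- crossprod(acts[[l]], delta)
    if (l <= 2L && config$l2 > 0) gW <- gW + 2 * config$l2 * weights[[l]]$W
    grads[[l]] <- list(W = gW, b = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% t(weights[[l]]$W)) * (acts[[l]] > 0)  # ReLU mask
    }
  }
  grads
}

.mse <- function(pred, Y) mean((pred - Y)^2)

#' Train the prediction head
#'
#' Runs mini-batch Adam on MSE for at most `config$max_epochs` epochs,
#' re-balancing and re-shuffling the training examples before each epoch.
#' Validation loss is computed on the full (unbalanced) validation set
#' after every epoch; the weights with the lowest validation loss are
#' kept, and training stops early after `config$patience` epochs without
#' improvement. Fully reproducible given `config$seed`.
#'
#' @param config A [head_config()].
#' @param train,validation Participant-disjoint `labelled_dataset`s.
#' @param backend_name,backend_dim Recorded in the artifact so inference
#'   can refuse a mismatched backend.
#' @param verbose Print per-epoch losses.
#' @return A list of class `trained_head`: `weights`, `config`, `backend`,
#'   `history` (data.frame epoch/train_loss/val_loss), `best_epoch`.
#' @export
train_head <- function(config, train, validation,
                       backend_name = "mel-stats",
                       backend_dim = config$input_dim - 1L,
                       verbose = FALSE) {
  stopifnot(inherits(config, "head_config"),
            inherits(train, "labelled_dataset"),
            inherits(validation, "labelled_dataset"))
  if (length(intersect(train$participant, validation$participant)) > 0) {
    stopf("train and validation share participants; split_by_participant() first")
  }
  if (ncol(train$features) != config$input_dim) {
    stopf("feature dim %d does not match config input_dim %d",
          ncol(train$features), config$input_dim)
  }
  if (nrow(train$features) == 0 || nrow(validation$features) == 0) {
    stopf("train and validation must be non-empty")
  }

  scaler <- .fit_scaler(train$features)
  train <- labelled_dataset(.apply_scaler(train$features, scaler),
                            train$labels, train$participant)
  X_val <- .apply_scaler(validation$features, scaler)

  weights <- .init_weights(config)
  adam <- .adam_init(weights)
  step <- 0L
  best <- list(loss = Inf, weights = weights, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  stale <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    order_idx <- balance_and_shuffle(train, derive_seed(config$seed, epoch))
    Xe <- train$features[order_idx, , drop = FALSE]
    Ye <- train$labels[order_idx, , drop = FALSE]
    n <- nrow(Xe)
    batch_losses <- numeric(0)
    for (b0 in seq(1L, n, by = config$batch_size)) {
      sel <- b0:min(b0 + config$batch_size - 1L, n)
      cache <- .forward(weights, Xe[sel, , drop = FALSE], keep_cache = TRUE)
      batch_losses <- c(batch_losses, .mse(cache$out, Ye[sel, , drop = FALSE]))
      grads <- .backward(weights, cache, Ye[sel, , drop = FALSE], config)
      step <- step + 1L
      upd <- .adam_step(weights, grads, adam, step, config$learning_rate)
      weights <- upd$weights; adam <- upd$state
    }
    val_loss <- .mse(.forward(weights, X_val), validation$labels)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(batch_losses),
                                         val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      mean(batch_losses), val_loss))
    }
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, weights = weights, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (is.finite(config$patience) && stale >= config$patience) break
    }
  }

  structure(list(weights = best$weights, scaler = scaler, config = config,
                 backend = list(name = backend_name, dim = as.integer(backend_dim)),
                 history = history, best_epoch = best$epoch),
            class = "trained_head")
}

.adam_init <- function(weights) {
  list(m = lapply(weights, function(w) list(W = w$W * 0, b = w$b * 0)),
       v = lapply(weights, function(w) list(W = w$W * 0, b = w$b * 0)))
}

.adam_step <- function(weights, grads, state, step, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^step
  bc2 <- 1 - beta2^step
  for (l in seq_along(weights)) {
    for (part in c("W", "b")) {
      g <- grads[[l]][[part]]
      state$m[[l]][[part]] <- beta1 * state$m[[l]][[part]] + (1 - beta1) * g
      state$v[[l]][[part]] <- beta2 * state$v[[l]][[part]] + (1 - beta2) * g^2
      m_hat <- state$m[[l]][[part]] / bc1
      v_hat <- state$v[[l]][[part]] / bc2
      weights[[l]][[part]] <- weights[[l]][[part]] - lr * m_hat / (sqrt(v_hat) + eps)
    }
  }
  list(weights = weights, state = state)
}

#' @export
print.trained_head <- function(x, ...) {
  cat(sprintf("<trained_head: %s -> %s -> %d, backend '%s' (dim %d), best epoch %d (val %.5f)>\n",
              x$config$input_dim, paste(x$config$hidden, collapse = "-"),
              x$config$output_dim, x$backend$name, x$backend$dim,
              x$best_epoch, min(x$history$val_loss)))
  invisible(x)
}

#' Predict subframe confidences
#'
#' @param head A `trained_head`.
#' @param features A feature vector, or a matrix with one vector per row.
#' @return For a single vector, six confidences in (0, 1); for a matrix,
#'   a matrix with six columns.
#' @export
predict_head <- function(head, features) {
  stopifnot(inherits(head, "trained_head"))
  single <- is.null(dim(features))
  X <- if (single) matrix(features, nrow = 1) else as.matrix(features)
  if (ncol(X) != head$config$input_dim) {
    stopf("feature length %d does not match head input_dim %d",
          ncol(X), head$config$input_dim)
  }
  out <- .forward(head$weights, .apply_scaler(X, head$scaler))
  if (single) as.numeric(out) else out
}

#' Save a trained head to disk
#'
#' The artifact is a JSON file holding the architecture, training
#' configuration, backend name/dim and full-precision weights; loading
#' verifies backend compatibility. Plain text, portable across machines.
#'
#' @param head A `trained_head`.
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_head <- function(head, path) {
  stopifnot(inherits(head, "trained_head"))
  obj <- list(
    format = "swallowseg-head-1",
    config = unclass(head$config),
    scaler = head$scaler,
    backend = head$backend,
    best_epoch = head$best_epoch,
    history = head$history,
    weights = lapply(head$weights, function(w) {
      list(W = as.numeric(w$W), dim = dim(w$W), b = w$b)
    })
  )
  # I(17) significant digits: doubles survive the text round trip exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Load a trained head
#'
#' @param path Artifact path written by [save_head()].
#' @param expect_backend Optional backend name that must match the
#'   artifact's recorded backend (inference refuses a mismatch).
#' @return A `trained_head`.
#' @export
load_head <- function(path, expect_backend = NULL) {
  if (!file.exists(path)) stopf("model artifact not found: '%s'", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "swallowseg-head-1")) {
    stopf("'%s' is not a swallowseg head artifact", path)
  }
  if (!is.null(expect_backend) && !identical(obj$backend$name, expect_backend)) {
    stopf("artifact was trained with backend '%s' but '%s' was requested",
          obj$backend$name, expect_backend)
  }
  cfg <- obj$config
  config <- head_config(cfg$input_dim, cfg$hidden, cfg$output_dim, cfg$l2,
                        cfg$learning_rate, cfg$batch_size, cfg$max_epochs,
                        if (is.null(cfg$patience) || cfg$patience == "Inf") Inf else cfg$patience,
                        cfg$seed)
  weights <- lapply(seq_len(nrow(obj$weights)), function(l) {
    row <- obj$weights[l, ]
    list(W = matrix(row$W[[1]], nrow = row$dim[[1]][1], ncol = row$dim[[1]][2]),
         b = as.numeric(row$b[[1]]))
  })
  scaler <- if (!is.null(obj$scaler)) {
    list(mean = as.numeric(obj$scaler$mean), sd = as.numeric(obj$scaler$sd))
  }
  structure(list(weights = weights, scaler = scaler, config = config,
                 backend = list(name = obj$backend$name,
                                dim = as.integer(obj$backend$dim)),
                 history = as.data.frame(obj$history),
                 best_epoch = obj$best_epoch),
            class = "trained_head")
}
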