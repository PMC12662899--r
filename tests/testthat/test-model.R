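# Head training: splitting, balancing, optimization, prediction,
# serialization. Small architectures are used where the property under
# test does not depend on layer sizes, to keep the suite quick.

make_dataset <- function(n, input_dim = 20, participants = 4, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * input_dim), n)
  # separable rule: labels follow the sign of the first six features,
  # with half the rows forced all-negative there (non-swallow frames)
  neg_rows <- seq_len(n) > n / 2
  X[neg_rows, 1:6] <- -abs(X[neg_rows, 1:6]) - 0.1
  Y <- matrix(as.integer(X[, 1:6] > 0), n)
  labelled_dataset(X, Y, rep_len(sprintf("p%02d", seq_len(participants)), n))
}

small_config <- function(...) {
  head_config(input_dim = 20, hidden = c(32, 32, 16), ...)
}

test_that("split_by_participant partitions participants 80/20, disjointly", {
  ds <- make_dataset(200, participants = 10)
  sp <- split_by_participant(ds, 0.8, seed = 3)
  expect_length(unique(sp$train$participant), 8)
  expect_length(unique(sp$validation$participant), 2)
  expect_length(intersect(sp$train$participant, sp$validation$participant), 0)
  expect_equal(nrow(sp$train$features) + nrow(sp$validation$features), 200)

  ds2 <- make_dataset(40, participants = 2)
  sp2 <- split_by_participant(ds2, 0.8, seed = 1)
  expect_length(unique(sp2$train$participant), 1)
  expect_length(unique(sp2$validation$participant), 1)

  ds1 <- make_dataset(40, participants = 1)
  expect_error(split_by_participant(ds1), "2 distinct participants")
})

test_that("balance_and_shuffle undersamples the majority group", {
  X <- matrix(rnorm(400 * 5), 400)
  Y <- rbind(matrix(1L, 100, 6), matrix(0L, 300, 6))
  ds <- labelled_dataset(X, Y, "p")
  idx <- balance_and_shuffle(ds, 7)
  expect_length(idx, 200)
  expect_equal(sum(rowSums(ds$labels[idx, ]) > 0), 100)
  expect_equal(sum(rowSums(ds$labels[idx, ]) == 0), 100)
  expect_identical(idx, balance_and_shuffle(ds, 7))      # same seed
  expect_false(identical(idx, balance_and_shuffle(ds, 8)))

  # already balanced: everything retained, order permuted
  ds5050 <- labelled_dataset(matrix(rnorm(100 * 5), 100),
                             rbind(matrix(1L, 50, 6), matrix(0L, 50, 6)), "p")
  idx2 <- balance_and_shuffle(ds5050, 1)
  expect_setequal(idx2, 1:100)

  all_zero <- labelled_dataset(X, matrix(0L, 400, 6), "p")
  expect_error(balance_and_shuffle(all_zero, 1), "degenerate")
})

test_that("training reduces loss and is bitwise reproducible", {
  ds <- make_dataset(120, participants = 4)
  sp <- split_by_participant(ds, 0.75, seed = 2)
  cfg <- small_config(max_epochs = 30, seed = 5)
  h1 <- train_head(cfg, sp$train, sp$validation)
  expect_lt(tail(h1$history$train_loss, 1), h1$history$train_loss[1])
  expect_lte(nrow(h1$history), 30)

  h2 <- train_head(cfg, sp$train, sp$validation)
  expect_identical(h1$history, h2$history)
  expect_identical(h1$weights, h2$weights)

  # participant overlap is refused outright
  expect_error(train_head(cfg, sp$train, sp$train), "participants")
})

test_that("training overfits a small separable set with the full architecture", {
  ds <- make_dataset(32, input_dim = 1025, participants = 1, seed = 9)
  ds <- labelled_dataset(ds$features, ds$labels, "train_p")
  probe <- labelled_dataset(ds$features, ds$labels, "val_p")
  cfg <- head_config(input_dim = 1025, max_epochs = 100, patience = Inf, seed = 2)
  h <- train_head(cfg, ds, probe)
  mse <- mean((predict_head(h, ds$features) - ds$labels)^2)
  expect_lt(mse, 0.05)
})

test_that("predict_head returns six confidences strictly inside (0,1)", {
  ds <- make_dataset(60, participants = 2)
  sp <- split_by_participant(ds, 0.5, seed = 1)
  h <- train_head(small_config(max_epochs = 3, seed = 1), sp$train,
                  sp$validation)
  p <- predict_head(h, ds$features[1, ])
  expect_length(p, 6)
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, predict_head(h, ds$features[1, ]))
  pm <- predict_head(h, ds$features)
  expect_equal(dim(pm), c(60, 6))
  expect_true(all(pm > 0 & pm < 1))
  expect_error(predict_head(h, rnorm(7)), "input_dim")

  # zeroed final layer puts every sigmoid at exactly 0.5
  h0 <- h
  L <- length(h0$weights)
  h0$weights[[L]]$W[] <- 0
  h0$weights[[L]]$b[] <- 0
  expect_equal(as.numeric(predict_head(h0, ds$features[3, ])), rep(0.5, 6))
})

test_that("save_head/load_head round-trips predictions exactly", {
  d <- withr::local_tempdir()
  ds <- make_dataset(60, participants = 2)
  sp <- split_by_participant(ds, 0.5, seed = 1)
  h <- train_head(small_config(max_epochs = 5, seed = 4), sp$train,
                  sp$validation, backend_name = "mel-stats",
                  backend_dim = 19L)
  p <- file.path(d, "head.json")
  save_head(h, p)
  h2 <- load_head(p)
  probe <- ds$features[1:10, ]
  expect_identical(predict_head(h2, probe), predict_head(h, probe))
  expect_equal(h2$backend, h$backend)
  expect_error(load_head(p, expect_backend = "yamnet"), "mel-stats")
})
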