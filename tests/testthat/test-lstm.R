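test_that("backpropagation matches finite-difference gradients", {
  cfg <- lstm_config(input_size = 3, hidden_units = 4, min_batch_size = 5,
                     max_epochs = 1, seq_len = 2, seed = 7)
  set.seed(7)
  params <- eegfocus:::lstm_init(cfg)
  X <- array(rnorm(5 * 2 * 3), dim = c(5, 2, 3))
  y <- c(1L, 2L, 1L, 2L, 2L)
  fwd <- eegfocus:::lstm_forward(params, X, cfg, cache = TRUE)
  grads <- eegfocus:::lstm_backward(params, X, y, cfg, fwd)
  loss_at <- function(p) {
    f <- eegfocus:::lstm_forward(p, X, cfg)
    eegfocus:::lstm_loss(f$probs, y)
  }
  eps <- 1e-6
  for (k in names(params)) {
    idx <- sample(length(params[[k]]), min(5, length(params[[k]])))
    for (i in idx) {
      pp <- params; pp[[k]][i] <- pp[[k]][i] + eps
      pm <- params; pm[[k]][i] <- pm[[k]][i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(grads[[k]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("gradient clipping caps the global norm and only when needed", {
  g <- list(a = matrix(3, 2, 2), b = rep(4, 3))
  clipped <- eegfocus:::clip_gradients(g, 2)
  gn <- sqrt(sum(unlist(clipped)^2))
  expect_equal(gn, 2, tolerance = 1e-12)
  small <- list(a = matrix(0.1, 2, 2))
  expect_identical(eegfocus:::clip_gradients(small, 2), small)
})

test_that("training separates a well-separated two-class task", {
  fm <- make_separable_features(n_per_class = 60, seed = 3)
  sp <- split_dataset(fm, split_spec(seed = 5))
  cfg <- lstm_config(hidden_units = 32, max_epochs = 40,
                     min_batch_size = 30, seed = 11)
  model <- train_classifier(sp$train, sp$validation, cfg)
  expect_gte(model$val_accuracy, 0.95)
  pred_tr <- predict_epochs(model, sp$train)
  expect_gte(mean(pred_tr$labels == sp$train$labels), 0.95)
  pred_te <- predict_epochs(model, sp$test)
  expect_gte(mean(pred_te$labels == sp$test$labels), 0.90)
})

test_that("training is deterministic given the seed", {
  fm <- make_separable_features(n_per_class = 20, seed = 2)
  sp <- split_dataset(fm, split_spec(seed = 5))
  cfg <- lstm_config(hidden_units = 8, max_epochs = 5,
                     min_batch_size = 10, seed = 42)
  m1 <- train_classifier(sp$train, sp$validation, cfg)
  m2 <- train_classifier(sp$train, sp$validation, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("prediction returns normalized scores and handles edge cases", {
  fm <- make_separable_features(n_per_class = 20, seed = 2)
  sp <- split_dataset(fm, split_spec(seed = 5))
  cfg <- lstm_config(hidden_units = 8, max_epochs = 3,
                     min_batch_size = 10, seed = 1)
  model <- train_classifier(sp$train, sp$validation, cfg)
  pred <- predict_epochs(model, sp$test)
  expect_equal(rowSums(pred$scores), rep(1, nrow(pred$scores)),
               tolerance = 1e-6)
  expect_true(all(pred$labels %in% c("ictal", "interictal")))

  empty <- eegfocus:::subset_features(fm, integer(0))
  out <- predict_epochs(model, empty)
  expect_length(out$labels, 0)
  expect_equal(nrow(out$scores), 0)

  wide <- fm; wide$energy <- cbind(fm$energy, fm$energy[, 1])
  expect_error(predict_epochs(model, wide), class = "config_error")
  expect_error(train_classifier(wide, sp$validation, cfg),
               class = "config_error")
})

test_that("single-class training data is rejected", {
  fm <- make_separable_features(n_per_class = 20, seed = 2)
  only <- eegfocus:::subset_features(fm, which(fm$labels == "ictal"))
  expect_error(train_classifier(only, fm, lstm_config(max_epochs = 1)),
               class = "balancing_error")
})

test_that("a trained model survives save/load with identical predictions", {
  fm <- make_separable_features(n_per_class = 20, seed = 2)
  sp <- split_dataset(fm, split_spec(seed = 5))
  cfg <- lstm_config(hidden_units = 8, max_epochs = 3,
                     min_batch_size = 10, seed = 1)
  model <- train_classifier(sp$train, sp$validation, cfg)
  path <- file.path(withr::local_tempdir(), "model.json")
  save_classifier(model, path)
  back <- load_classifier(path)
  p1 <- predict_epochs(model, sp$test)
  p2 <- predict_epochs(back, sp$test)
  expect_equal(p2$scores, p1$scores, tolerance = 1e-12)
})
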