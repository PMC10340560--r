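# A small LSTM classifier in base R matrix code: one LSTM layer, a fully
# connected layer, softmax, cross-entropy, Adam with gradient-norm clipping.
# Each epoch's per-channel band-energy vector is presented as a length-1
# sequence by default (feature input -> LSTM -> FC -> softmax); longer
# sequences of consecutive epochs are available via seq_len.

#' LSTM classifier configuration
#'
#' Hyperparameters of the ictal/interictal classifier. Defaults mirror a
#' compact configuration that works well for 16-channel band-energy
#' features: 128 hidden units, mini-batches of 150, at most 100 passes over
#' the training data, Adam at learning rate 0.001 with the global gradient
#' norm clipped at 2.
#'
#' @param input_size feature dimension (16 lateral channels, or 18).
#' @param hidden_units LSTM state size.
#' @param n_classes number of output classes (2).
#' @param min_batch_size mini-batch size.
#' @param max_epochs maximum training passes.
#' @param learning_rate initial Adam learning rate.
#' @param gradient_threshold global L2 clipping threshold for gradients.
#' @param seq_len epochs per input sequence (1 = each epoch classified from
#'   its own feature vector; >1 feeds consecutive epochs of a recording).
#' @param seed integer seed for initialization and batch shuffling.
#' @return An object of class `lstm_config`.
#' @export
lstm_config <- function(input_size = 16L, hidden_units = 128L,
                        n_classes = 2L, min_batch_size = 150L,
                        max_epochs = 100L, learning_rate = 1e-3,
                        gradient_threshold = 2, seq_len = 1L, seed = 1L) {
  cfg <- list(input_size = as.integer(input_size),
              hidden_units = as.integer(hidden_units),
              n_classes = as.integer(n_classes),
              min_batch_size = as.integer(min_batch_size),
              max_epochs = as.integer(max_epochs),
              learning_rate = learning_rate,
              gradient_threshold = gradient_threshold,
              seq_len = as.integer(seq_len),
              seed = as.integer(seed))
  if (any(unlist(cfg[c("input_size", "hidden_units", "min_batch_size",
                       "max_epochs", "seq_len")]) < 1L) ||
      cfg$learning_rate <= 0 || cfg$gradient_threshold <= 0)
    stop_eegfocus("all LSTM configuration values must be positive",
                  "config_error")
  if (cfg$n_classes != 2L)
    stop_eegfocus("the classifier is binary (n_classes = 2)", "config_error")
  class(cfg) <- "lstm_config"
  cfg
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Gate layout in the concatenated weight matrices: [input, forget, cell, output]
lstm_init <- function(cfg) {
  D <- cfg$input_size; H <- cfg$hidden_units; C <- cfg$n_classes
  gl <- function(nin, nout) {
    s <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * nout, -s, s), nin, nout)
  }
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1   # forget-gate bias at 1: standard LSTM practice
  list(W = gl(D, 4 * H), R = gl(H, 4 * H), b = b,
       Wout = gl(H, C), bout = rep(0, C))
}

# Forward pass. X: array B x T x D. Returns softmax probabilities and,
# if cache = TRUE, the per-step activations needed for BPTT.
lstm_forward <- function(params, X, cfg, cache = FALSE) {
  B <- dim(X)[1L]; TT <- dim(X)[2L]; H <- cfg$hidden_units
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  steps <- if (cache) vector("list", TT) else NULL
  for (t in seq_len(TT)) {
    xt <- matrix(X[, t, ], nrow = B)
    Z <- xt %*% params$W + h %*% params$R +
      matrix(params$b, B, 4 * H, byrow = TRUE)
    i <- sigmoid(Z[, 1:H, drop = FALSE])
    f <- sigmoid(Z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(Z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(Z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    if (cache)
      steps[[t]] <- list(x = xt, i = i, f = f, g = g, o = o,
                         cprev = cc, hprev = h, tc = tc)
    cc <- c_new
    h <- o * tc
  }
  logits <- h %*% params$Wout +
    matrix(params$bout, B, cfg$n_classes, byrow = TRUE)
  m <- apply(logits, 1L, max)
  ex <- exp(logits - m)
  probs <- ex / rowSums(ex)
  list(probs = probs, h = h, steps = steps)
}

# Cross-entropy gradient via backpropagation through time.
# y: integer class index per row. Returns gradients shaped like params.
lstm_backward <- function(params, X, y, cfg, fwd) {
  B <- dim(X)[1L]; TT <- dim(X)[2L]; H <- cfg$hidden_units
  dlogits <- fwd$probs
  dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
  dlogits <- dlogits / B
  gWout <- t(fwd$h) %*% dlogits
  gbout <- colSums(dlogits)
  dh <- dlogits %*% t(params$Wout)
  dc <- matrix(0, B, H)
  gW <- array(0, dim(params$W)); gR <- array(0, dim(params$R))
  gb <- rep(0, 4 * H)
  for (t in rev(seq_len(TT))) {
    st <- fwd$steps[[t]]
    do <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$cprev
    dZ <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do * st$o * (1 - st$o))
    gW <- gW + t(st$x) %*% dZ
    gR <- gR + t(st$hprev) %*% dZ
    gb <- gb + colSums(dZ)
    dh <- dZ %*% t(params$R)
    dc <- dc * st$f
  }
  list(W = gW, R = gR, b = gb, Wout = gWout, bout = gbout)
}

lstm_loss <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y)], 1e-12)))
}

clip_gradients <- function(grads, threshold) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (is.finite(gn) && gn > threshold)
    grads <- lapply(grads, function(g) g * (threshold / gn))
  grads
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

CLASS_LEVELS <- c("ictal", "interictal")

# Band energies are approximately log-normal, so the network sees
# z-scored log-energies (training-split statistics).
log_energy <- function(E) log(E + 1e-12)

# Assemble the network input from a feature matrix: standardized
# log-energies, shaped B x seq_len x D. For seq_len > 1 each epoch is
# preceded by its seq_len - 1 predecessors within the same recording
# (edge epochs repeat their earliest available predecessor).
features_to_input <- function(fm, mu, sd, slen = 1L) {
  Xs <- sweep(sweep(log_energy(fm$energy), 2L, mu), 2L, sd, "/")
  n <- nrow(Xs); D <- ncol(Xs)
  X <- array(0, dim = c(n, slen, D))
  if (slen == 1L) {
    X[, 1L, ] <- Xs
    return(X)
  }
  for (r in unique(fm$origin$recording_id)) {
    rows <- which(fm$origin$recording_id == r)
    rows <- rows[order(fm$origin$start_sample[rows])]
    for (j in seq_along(rows)) {
      back <- rows[max(1L, j - (slen - 1L)):j]
      back <- c(rep(back[1L], slen - length(back)), back)
      X[rows[j], , ] <- Xs[back, , drop = FALSE]
    }
  }
  X
}

#' Train the ictal/interictal LSTM classifier
#'
#' Standardizes features per channel (z-scored log-energies with
#' training-split statistics; band power is approximately log-normal, and
#' the raw energies span orders of magnitude), then trains the LSTM by
#' mini-batch Adam with seeded
#' initialization and shuffling. Validation accuracy is computed after
#' every training pass and the parameters of the best-validation pass are
#' returned (ties resolved to the earliest).
#'
#' @param train,validation `feature_matrix` splits (train should already be
#'   balanced; see [balance_by_duplication()]).
#' @param cfg an [lstm_config()]; `input_size` must equal the feature
#'   dimension.
#' @return An object of class `seizure_lstm`: list with `params`, `cfg`,
#'   `mu`, `sd`, `classes`, and `history` (per-pass loss and validation
#'   accuracy).
#' @export
train_classifier <- function(train, validation, cfg = lstm_config()) {
  D <- ncol(train$energy)
  if (D != cfg$input_size)
    stop_eegfocus(sprintf("feature dimension %d != cfg$input_size %d",
                          D, cfg$input_size), "config_error")
  if (length(unique(train$labels)) < 2L)
    stop_eegfocus("training data must contain both classes", "balancing_error")
  old <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(cfg$seed)

  mu <- colMeans(log_energy(train$energy))
  sd <- apply(log_energy(train$energy), 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1

  Xtr <- features_to_input(train, mu, sd, cfg$seq_len)
  ytr <- match(train$labels, CLASS_LEVELS)
  Xva <- features_to_input(validation, mu, sd, cfg$seq_len)
  yva <- match(validation$labels, CLASS_LEVELS)

  params <- lstm_init(cfg)
  opt <- adam_init(params)
  best <- list(acc = -Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_accuracy = numeric(0))
  n <- dim(Xtr)[1L]
  for (ep in seq_len(cfg$max_epochs)) {
    perm <- sample(n)
    losses <- numeric(0)
    for (b0 in seq(1L, n, by = cfg$min_batch_size)) {
      idx <- perm[b0:min(b0 + cfg$min_batch_size - 1L, n)]
      Xb <- Xtr[idx, , , drop = FALSE]
      yb <- ytr[idx]
      fwd <- lstm_forward(params, Xb, cfg, cache = TRUE)
      losses <- c(losses, lstm_loss(fwd$probs, yb))
      grads <- lstm_backward(params, Xb, yb, cfg, fwd)
      grads <- clip_gradients(grads, cfg$gradient_threshold)
      upd <- adam_step(params, grads, opt, cfg$learning_rate)
      params <- upd$params; opt <- upd$state
    }
    va <- lstm_forward(params, Xva, cfg)
    acc <- mean(max.col(va$probs) == yva)
    history <- rbind(history, data.frame(epoch = ep, loss = mean(losses),
                                         val_accuracy = acc))
    if (acc > best$acc) best <- list(acc = acc, params = params, epoch = ep)
  }
  structure(list(params = best$params, cfg = cfg, mu = mu, sd = sd,
                 classes = CLASS_LEVELS, history = history,
                 best_epoch = best$epoch,
                 val_accuracy = best$acc),
            class = "seizure_lstm")
}

#' @export
print.seizure_lstm <- function(x, ...) {
  cat(sprintf(
    "LSTM seizure classifier: %d -> %d hidden -> %d classes; best val accuracy %.4f (pass %d/%d)\n",
    x$cfg$input_size, x$cfg$hidden_units, x$cfg$n_classes,
    x$val_accuracy, x$best_epoch, nrow(x$history)))
  invisible(x)
}

#' Classify epochs with a trained model
#'
#' @param model a [train_classifier()] result.
#' @param fm a `feature_matrix` with the model's feature dimension.
#' @return list with `labels` (character) and `scores` (n x 2 matrix of
#'   class probabilities, columns `ictal`, `interictal`, rows summing to 1).
#' @export
predict_epochs <- function(model, fm) {
  if (nrow(fm$energy) == 0L)
    return(list(labels = character(0),
                scores = matrix(0, 0, 2,
                                dimnames = list(NULL, model$classes))))
  if (ncol(fm$energy) != model$cfg$input_size)
    stop_eegfocus("feature dimension does not match the model",
                  "config_error")
  X <- features_to_input(fm, model$mu, model$sd, model$cfg$seq_len)
  fwd <- lstm_forward(model$params, X, model$cfg)
  colnames(fwd$probs) <- model$classes
  list(labels = model$classes[max.col(fwd$probs)], scores = fwd$probs)
}

#' Save / load a trained classifier
#'
#' Plain-JSON serialization of the parameters, configuration and
#' standardization statistics.
#'
#' @param model a `seizure_lstm`.
#' @param path file path.
#' @return `path` (save) or the restored `seizure_lstm` (load).
#' @export
save_classifier <- function(model, path) {
  obj <- list(params = lapply(model$params, function(p)
                if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
                else list(dim = length(p), data = as.numeric(p))),
              cfg = unclass(model$cfg), mu = model$mu, sd = model$sd,
              classes = model$classes, best_epoch = model$best_epoch,
              val_accuracy = model$val_accuracy)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1L], p$dim[2L])
    else as.numeric(p$data)
  })
  cfg <- do.call(lstm_config, obj$cfg)
  structure(list(params = params, cfg = cfg,
                 mu = obj$mu, sd = obj$sd, classes = obj$classes,
                 history = NULL, best_epoch = obj$best_epoch,
                 val_accuracy = obj$val_accuracy),
            class = "seizure_lstm")
}
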