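#' Training configuration
#'
#' Settings for the supervised training loop: Adam with a constant learning
#' rate, L1 regularization of all trainable parameters, global gradient-norm
#' clipping, fresh generative batches every step, periodic validation on
#' freshly drawn examples, and rolling-average stopping rules.
#'
#' @param learning_rate Adam learning rate (default `1e-3`; Adam moment
#'   decays are the standard 0.9 / 0.999 with `eps = 1e-8`).
#' @param l1 L1 regularization coefficient on trainable parameters
#'   (default `1e-4`).
#' @param grad_clip Global gradient-norm ceiling (default 10).
#' @param batch_size Training batch size (default 32, the one minibatch
#'   size the training protocol states explicitly).
#' @param validation_interval Batches between validation measurements
#'   (default 10).
#' @param validation_size Freshly generated examples per validation
#'   measurement (default 250; a rolling average over the default window
#'   therefore aggregates 2500 fresh examples per stopping decision).
#' @param rolling_window Validation measurements in the rolling average
#'   (default 10, i.e. 100 batches at the default interval).
#' @param min_batches Minimum training batches before any stop rule can
#'   fire (default 2000).
#' @param max_batches Hard cap on training batches (default 10000).
#' @param stop_rule `"accuracy"` (rolling validation accuracy reaches
#'   `acc_threshold`), `"plateau"` (rolling validation loss saturated, see
#'   [rolling_validation()]), `"either"` (whichever of those two fires
#'   first), or `"max"` (run to `max_batches`).
#' @param acc_threshold Accuracy threshold for the accuracy rule
#'   (default 0.98).
#' @param plateau_patience Validation checks without a new rolling-loss
#'   minimum before the plateau rule declares saturation (default 30,
#'   i.e. 300 batches; see [rolling_validation()]).
#' @return An object of class `"mpn_train_config"`.
#' @export
train_config <- function(learning_rate = 1e-3, l1 = 1e-4, grad_clip = 10,
                         batch_size = 32, validation_interval = 10,
                         validation_size = 250, rolling_window = 10,
                         min_batches = 2000, max_batches = 10000,
                         stop_rule = c("accuracy", "plateau", "either",
                                       "max"),
                         acc_threshold = 0.98, plateau_patience = 30) {
  stop_rule <- match.arg(stop_rule)
  stopifnot(learning_rate >= 0, l1 >= 0, grad_clip > 0, batch_size >= 1,
            rolling_window >= 1, validation_interval >= 1,
            min_batches >= 0, max_batches >= 1, plateau_patience >= 1)
  structure(as.list(environment()), class = "mpn_train_config")
}

# ---- forward / gradient dispatch ----------------------------------------

# X: array d x T x B; returns list(Y [, H, Yall, M, Hgo])
forward_pass <- function(params, X, ret_H = FALSE, ret_Yall = FALSE,
                         m_times = integer(0), x_go = NULL) {
  cfg <- params$config
  if (!is.array(X) || length(dim(X)) != 3) dim(X) <- c(dim(X), 1)
  if (cfg$family %in% c("mpn", "feedforward")) {
    eta <- if (cfg$family == "mpn") params$eta else 0
    lam <- if (cfg$family == "mpn") params$lam else 0
    mpn_forward_cpp(params$W_inp, params$b, params$W_RO, params$b_RO,
                    eta, lam, X, rule_code(cfg$rule),
                    if (is.null(cfg$m_b)) -1 else cfg$m_b,
                    act_code(cfg$activation), ret_H, ret_Yall,
                    as.integer(m_times), !is.null(x_go),
                    if (is.null(x_go)) numeric(cfg$d) else x_go)
  } else if (cfg$family == "vanilla_rnn") {
    rnn_forward_cpp(params$W_inp, params$W_rec, params$b, params$W_RO,
                    params$b_RO, X, act_code(cfg$activation), ret_H, ret_Yall)
  } else {
    gru_forward_cpp(params$W_rec_u, params$W_inp_u, params$b_u,
                    params$W_rec_r, params$W_inp_r, params$b_r,
                    params$W_rec, params$W_inp, params$b,
                    params$W_RO, params$b_RO, X,
                    act_code(cfg$activation), ret_H, ret_Yall)
  }
}

# mean cross-entropy + accuracy + per-parameter gradients
grad_pass <- function(params, X, labels) {
  cfg <- params$config
  if (cfg$family %in% c("mpn", "feedforward")) {
    eta <- if (cfg$family == "mpn") params$eta else 0
    lam <- if (cfg$family == "mpn") params$lam else 0
    g <- mpn_grad_cpp(params$W_inp, params$b, params$W_RO, params$b_RO,
                      eta, lam, X, as.integer(labels), rule_code(cfg$rule),
                      if (is.null(cfg$m_b)) -1 else cfg$m_b,
                      act_code(cfg$activation))
    names(g) <- sub("^geta$", "g.eta", sub("^glam$", "g.lam", names(g)))
    names(g) <- sub("^g(W|b)", "g.\\1", names(g))
  } else if (cfg$family == "vanilla_rnn") {
    g <- rnn_grad_cpp(params$W_inp, params$W_rec, params$b, params$W_RO,
                      params$b_RO, X, as.integer(labels),
                      act_code(cfg$activation))
    names(g) <- sub("^g(W|b)", "g.\\1", names(g))
  } else {
    g <- gru_grad_cpp(params$W_rec_u, params$W_inp_u, params$b_u,
                      params$W_rec_r, params$W_inp_r, params$b_r,
                      params$W_rec, params$W_inp, params$b,
                      params$W_RO, params$b_RO, X, as.integer(labels),
                      act_code(cfg$activation))
    names(g) <- sub("^g(W|b)", "g.\\1", names(g))
  }
  grads <- g[startsWith(names(g), "g.")]
  names(grads) <- sub("^g\\.", "", names(grads))
  list(loss = g$loss, acc = g$acc, grads = grads)
}

ce_loss <- function(Y, labels) {
  # Y: N x B outputs; mean softmax cross-entropy
  Ym <- sweep(Y, 2, apply(Y, 2, max))
  p <- exp(Ym)
  p <- sweep(p, 2, colSums(p), "/")
  idx <- cbind(labels, seq_along(labels))
  mean(-log(pmax(p[idx], 1e-300)))
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params, trainable) {
  list(m = lapply(params[trainable], function(p) p * 0),
       v = lapply(params[trainable], function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- stopping rules -----------------------------------------------------

#' Rolling-average stopping rules
#'
#' The accuracy rule stops when the mean of the last `window` validation
#' accuracies reaches `threshold`. The plateau rule tracks the rolling
#' average of the validation loss (window of `window` measurements, 100
#' batches at the default cadence) and declares the loss saturated when
#' that rolling average has not improved on its running minimum for
#' `patience` consecutive checks (default 30, i.e. 300 batches): a
#' direct two-window comparison turns out to be a near-coin-flip whenever
#' the loss slope is shallow relative to validation noise, and stops
#' training at transient saddles that further training escapes.
#' Insufficient history always means "continue".
#'
#' @param history Data frame with columns `batch`, `val_loss`, `val_acc`
#'   (one row per validation measurement, as produced by [train()]).
#' @param rule `"accuracy"`, `"plateau"`, `"either"` (accuracy or
#'   plateau, whichever fires first), or `"max"` (never stops early).
#' @param threshold Accuracy threshold for the accuracy rule.
#' @param window Rolling-window length in validation measurements.
#' @param min_batches Checks never fire before this many batches.
#' @param patience Plateau rule: checks without a new rolling-loss minimum
#'   before training is declared saturated.
#' @return `TRUE` if training should stop.
#' @export
rolling_validation <- function(history, rule = c("accuracy", "plateau",
                                                 "either", "max"),
                               threshold = 0.98, window = 10,
                               min_batches = 0, patience = 30) {
  rule <- match.arg(rule)
  k <- nrow(history)
  if (k == 0 || history$batch[k] < min_batches) return(FALSE)
  if (rule == "either") {
    return(rolling_validation(history, "accuracy", threshold, window) ||
             rolling_validation(history, "plateau", threshold, window,
                                patience = patience))
  }
  if (rule == "accuracy") {
    if (k < window) return(FALSE)
    return(mean(history$val_acc[(k - window + 1):k]) >= threshold)
  }
  if (rule == "plateau") {
    if (k < window + patience) return(FALSE)
    roll <- vapply(window:k, function(j) {
      mean(history$val_loss[(j - window + 1):j])
    }, 0)
    jmin <- which.min(roll) + window - 1L
    return(k - jmin >= patience)
  }
  FALSE
}

# ---- training loop ------------------------------------------------------

#' Train a network on a generative integration task
#'
#' Minimizes the softmax cross-entropy of the final-step output plus an L1
#' penalty on all trainable parameters, by Adam over freshly generated
#' batches. The gradient is clipped to a global norm of `grad_clip`, and
#' after every optimizer step the modulation decay `lam` is projected back
#' into `[0, lambda_max]`. Validation accuracy/loss are measured every
#' `validation_interval` batches on fresh examples and drive the stopping
#' rule. Deterministic given `seed`.
#'
#' @param config An [model_config()].
#' @param task An [task_spec()].
#' @param tc An [train_config()].
#' @param seed Integer seed covering initialization, task draws and noise.
#' @param codebook Optional codebook (defaults to [default_codebook()],
#'   drawn under the same seed); pass explicitly to share codewords across
#'   tasks.
#' @param params Optional warm-start parameters (skips initialization).
#' @param trainable Optional character vector of parameter names to update
#'   (defaults to all of the family's trainable parameters); anything else
#'   is frozen.
#' @param verbose Print validation progress?
#' @return An object of class `"mpn_fit"`: `params`, `history` (data frame
#'   of validation measurements), `stop_reason`, `batches`, plus the task,
#'   codebook and configs used.
#' @export
train <- function(config, task, tc = train_config(), seed = 1,
                  codebook = NULL, params = NULL, trainable = NULL,
                  verbose = FALSE) {
  stopifnot(inherits(config, "mpn_config"), inherits(task, "mpn_task"),
            inherits(tc, "mpn_train_config"))
  set.seed(as.integer(seed))
  if (is.null(codebook)) codebook <- default_codebook(task)
  if (is.null(params)) params <- init_params_rng(config)
  if (is.null(trainable)) trainable <- trainable_names(config)
  opt <- adam_init(params, trainable)
  hist_b <- integer(0); hist_l <- numeric(0); hist_a <- numeric(0)
  stop_reason <- "max_batches"
  i <- 0L
  while (i < tc$max_batches) {
    i <- i + 1L
    batch <- sample_batch(task, codebook, tc$batch_size)
    g <- grad_pass(params, batch$X, batch$labels)
    if (!is.finite(g$loss)) {
      stop_reason <- "diverged"
      i <- i - 1L
      break
    }
    grads <- g$grads[trainable]
    if (tc$l1 > 0) {
      for (nm in trainable) grads[[nm]] <- grads[[nm]] +
          tc$l1 * sign(params[[nm]])
    }
    gn <- sqrt(sum(vapply(grads, function(x) sum(x^2), 0)))
    if (gn > tc$grad_clip) {
      grads <- lapply(grads, function(x) x * (tc$grad_clip / gn))
    }
    upd <- adam_step(params, grads, opt, tc$learning_rate)
    cfgp <- params$config
    params <- upd$params
    opt <- upd$state
    if (cfgp$family == "mpn" && "lam" %in% trainable) {
      params$lam <- min(max(params$lam, 0), cfgp$lambda_max)
    }
    if (i %% tc$validation_interval == 0) {
      vb <- sample_batch(task, codebook, tc$validation_size)
      Y <- forward_pass(params, vb$X)$Y
      hist_b <- c(hist_b, i)
      hist_l <- c(hist_l, ce_loss(Y, vb$labels))
      hist_a <- c(hist_a, mean(max.col(t(Y)) == vb$labels))
      if (verbose && length(hist_b) %% 10 == 0) {
        message(sprintf("batch %d: val loss %.4f acc %.3f",
                        i, hist_l[length(hist_l)], hist_a[length(hist_a)]))
      }
      h <- data.frame(batch = hist_b, val_loss = hist_l, val_acc = hist_a)
      if (rolling_validation(h, tc$stop_rule, tc$acc_threshold,
                             tc$rolling_window, tc$min_batches,
                             tc$plateau_patience)) {
        stop_reason <- tc$stop_rule
        break
      }
    }
  }
  structure(list(params = params,
                 history = data.frame(batch = hist_b, val_loss = hist_l,
                                      val_acc = hist_a),
                 stop_reason = stop_reason, batches = i,
                 config = config, task = task, tc = tc,
                 codebook = codebook, seed = seed),
            class = "mpn_fit")
}

#' @export
print.mpn_fit <- function(x, ...) {
  cat(sprintf("<mpn_fit> %s on %s task: %d batches, stop = %s",
              x$config$family, x$task$mode, x$batches, x$stop_reason))
  if (nrow(x$history)) {
    cat(sprintf(", final val acc %.3f", tail(x$history$val_acc, 1)))
  }
  cat("\n")
  invisible(x)
}

#' Classification accuracy on fresh examples
#'
#' Generates `n_examples` fresh sequences from the task and reports the
#' fraction whose final-output argmax matches the label.
#'
#' @param params An `"mpn_params"` object (or an `"mpn_fit"`, whose params,
#'   task and codebook are used).
#' @param task,codebook Task and codebook (taken from the fit if omitted).
#' @param n_examples Number of fresh test examples (default 1000).
#' @param seed Optional seed for the test draw.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_accuracy <- function(params, task = NULL, codebook = NULL,
                              n_examples = 1000, seed = NULL) {
  if (inherits(params, "mpn_fit")) {
    if (is.null(task)) task <- params$task
    if (is.null(codebook)) codebook <- params$codebook
    params <- params$params
  }
  if (is.null(codebook)) codebook <- default_codebook(task)
  if (!is.null(seed)) set.seed(as.integer(seed))
  correct <- 0L
  left <- n_examples
  while (left > 0) {
    B <- min(left, 2000L)
    b <- sample_batch(task, codebook, B)
    Y <- forward_pass(params, b$X)$Y
    correct <- correct + sum(max.col(t(Y)) == b$labels)
    left <- left - B
  }
  correct / n_examples
}

# ---- specialized protocols ----------------------------------------------

#' Echo-state (reservoir) training
#'
#' Freezes every parameter at its initialization value except the readout
#' matrix (and readout bias if enabled) and trains to a validation-loss
#' plateau. For the MPN family the plasticity scalars are fixed at the
#' modest values `eta = 1`, `lam = lambda_max` so the frozen modulation
#' dynamics are active.
#'
#' @inheritParams train
#' @return An `"mpn_fit"`; all non-readout parameters equal their
#'   initialization values bitwise.
#' @export
echo_state_protocol <- function(config, task, tc = NULL, seed = 1,
                                codebook = NULL) {
  if (is.null(tc)) {
    tc <- train_config(stop_rule = "plateau", min_batches = 500,
                       max_batches = 4000)
  }
  tc$stop_rule <- "plateau"
  set.seed(as.integer(seed))
  if (is.null(codebook)) codebook <- default_codebook(task)
  params <- init_params_rng(config)
  if (config$family == "mpn") {
    params$eta <- 1.0
    params$lam <- config$lambda_max
  }
  trainable <- c("W_RO", if (config$readout_bias) "b_RO")
  train(config, task, tc, seed = seed + 1L, codebook = codebook,
        params = params, trainable = trainable)
}

#' Sequential-learning (catastrophic forgetting) protocol
#'
#' Trains on a two-class integration-delay task A to a rolling validation
#' accuracy threshold, records the accuracy on A, then continues training
#' the same network on a task B that reuses A's null and go codewords but
#' draws fresh evidence codewords (readouts shared between phases), and
#' re-measures the accuracy on A. Phase batches are of size 1 with a
#' reduced L1 coefficient of `1e-6`, and the run is flagged excluded if
#' either phase fails to reach the threshold within the sample cap.
#'
#' @inheritParams train
#' @param threshold Rolling validation accuracy threshold (default 0.97).
#' @param T,T_delay Task geometry (defaults 40 / 20).
#' @param max_samples Training-sample cap per phase (default 100000).
#' @param n_test Test examples for the accuracy measurements.
#' @return A list with `acc_A_before`, `acc_A_after`, `excluded`, and the
#'   two fits.
#' @export
sequential_learning_protocol <- function(config, seed = 1, threshold = 0.97,
                                         T = 40, T_delay = 20,
                                         max_samples = 100000,
                                         n_test = 500) {
  task <- task_spec("simple", N = 2, T = T, T_delay = T_delay, d = config$d)
  set.seed(as.integer(seed))
  cbA <- default_codebook(task)
  cbB <- cbA
  v <- sqrt(2 / config$d)
  for (s in c("evid1", "evid2")) {
    cbB$vectors[, s] <- v * (stats::runif(config$d) < 0.5)
  }
  tc <- train_config(batch_size = 1, l1 = 1e-6, stop_rule = "accuracy",
                     acc_threshold = threshold, min_batches = 2000,
                     max_batches = max_samples, validation_size = 200,
                     validation_interval = 100)
  fitA <- train(config, task, tc, seed = seed + 1L, codebook = cbA)
  acc_before <- evaluate_accuracy(fitA$params, task, cbA, n_test,
                                  seed = seed + 2L)
  fitB <- train(config, task, tc, seed = seed + 3L, codebook = cbB,
                params = fitA$params)
  acc_after <- evaluate_accuracy(fitB$params, task, cbA, n_test,
                                 seed = seed + 4L)
  excluded <- fitA$stop_reason != "accuracy" || fitB$stop_reason != "accuracy"
  list(acc_A_before = acc_before, acc_A_after = acc_after,
       excluded = excluded, fit_A = fitA, fit_B = fitB)
}

#' Novel-class probe
#'
#' Takes a network trained on a two-class task, introduces a third evidence
#' codeword it has never been trained on, and collects final states
#' (flattened `M_{T-1}` for the MPN family, `h_T` for RNNs) over fresh
#' three-class sequences. MPN states are PCA-reduced to `n` components so
#' that downstream decoders for the MPN and an RNN of the same hidden size
#' see equal dimensionality.
#'
#' @param fit An `"mpn_fit"` trained on an `N = 2` simple task.
#' @param m Number of probe sequences (default 1000).
#' @param seed Optional seed for the novel codeword and probe draw.
#' @return A list with `states` (`m x k` matrix, `k = n` for the MPN),
#'   `labels` (1..3), and `novel_symbol`.
#' @export
novel_class_probe <- function(fit, m = 1000, seed = NULL) {
  stopifnot(inherits(fit, "mpn_fit"), fit$task$N == 2)
  if (!is.null(seed)) set.seed(as.integer(seed))
  cfg <- fit$config
  cb <- fit$codebook
  v <- sqrt(2 / cfg$d)
  novel <- v * (stats::runif(cfg$d) < 0.5)
  cb$vectors <- cbind(cb$vectors[, c("evid1", "evid2")], evid3 = novel,
                      cb$vectors[, setdiff(colnames(cb$vectors),
                                           c("evid1", "evid2")), drop = FALSE])
  cb$symbols <- colnames(cb$vectors)
  task3 <- fit$task
  task3$N <- 3L
  b <- sample_batch(task3, cb, m)
  if (cfg$family %in% c("mpn", "feedforward")) {
    fw <- forward_pass(fit$params, b$X, m_times = task3$T - 1L)
    states <- t(fw$M[, 1, ])                      # m x (n d)
    # PCA scores via the m x m Gram matrix: with m << n d this is much
    # cheaper than a full SVD and yields identical projections
    ctr <- sweep(states, 2, colMeans(states))
    eg <- eigen(tcrossprod(ctr), symmetric = TRUE)
    k <- min(cfg$n, sum(eg$values > 1e-10))
    states <- eg$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(eg$values[seq_len(k)], 0)), k)
  } else {
    fw <- forward_pass(fit$params, b$X, ret_H = TRUE)
    states <- t(fw$H[, task3$T, ])                # m x n
  }
  list(states = states, labels = b$labels, novel_symbol = "evid3")
}
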