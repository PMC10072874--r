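#' Collect population states over a test set
#'
#' Runs `m` fresh task sequences through a trained network and stacks the
#' requested activity into a row-per-(example, time) matrix with aligned
#' annotations, the common input to all state-space analyses. `"hidden"`
#' collects `h_t` for `t = 1..T` (columns = `n` neurons); `"modulation"`
#' (MPN family only) collects flattened SM matrices `M_t` for `t = 0..T`
#' (columns = `n d` synapses).
#'
#' @param fit An `"mpn_fit"` (or pass `params`, `task`, `codebook`
#'   explicitly).
#' @param m Number of test sequences.
#' @param which `"hidden"` or `"modulation"`.
#' @param times Optional integer subset of time steps to record (1..T for
#'   hidden, 0..T for modulation states).
#' @param seed Optional seed for the test draw.
#' @param params,task,codebook Overrides for the fit's components.
#' @return An object of class `"mpn_states"`: `X` (rows = collected
#'   states), `ann` (data frame with `example`, `t`, `label`, `symbol`,
#'   `rel_evidence` — the running class-1 minus class-2 evidence count up
#'   to and including `t`), and bookkeeping fields.
#' @export
collect_states <- function(fit = NULL, m = 1000,
                           which = c("hidden", "modulation"),
                           times = NULL, seed = NULL,
                           params = NULL, task = NULL, codebook = NULL) {
  which <- match.arg(which)
  if (!is.null(fit)) {
    if (is.null(params)) params <- fit$params
    if (is.null(task)) task <- fit$task
    if (is.null(codebook)) codebook <- fit$codebook
  }
  cfg <- params$config
  if (which == "modulation" && !cfg$family %in% c("mpn", "feedforward")) {
    stop("modulation states exist only for the MPN family", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  b <- sample_batch(task, codebook, m)
  Tn <- task$T
  # running relative evidence (class 1 - class 2), inclusive of step t
  rel <- apply(b$symbols, 2, function(s) {
    cumsum(s %in% c("evid1", "s1_evid1")) - cumsum(s %in% c("evid2", "s1_evid2"))
  })
  if (which == "hidden") {
    if (is.null(times)) times <- seq_len(Tn)
    H <- forward_pass(params, b$X, ret_H = TRUE)$H
    X <- matrix(NA_real_, m * length(times), cfg$n)
    for (k in seq_along(times)) {
      X[(k - 1) * m + seq_len(m), ] <- t(H[, times[k], ])
    }
    # rows are ordered time-major: all examples at times[1], then times[2], ...
    sym <- as.vector(t(b$symbols)[, times, drop = FALSE])
    relv <- as.vector(t(rel)[, times, drop = FALSE])
  } else {
    if (is.null(times)) times <- 0:Tn
    Ms <- forward_pass(params, b$X, m_times = times)$M
    X <- matrix(NA_real_, m * length(times), cfg$n * cfg$d)
    for (k in seq_along(times)) {
      X[(k - 1) * m + seq_len(m), ] <- t(Ms[, k, ])
    }
    symfull <- rbind(".init", b$symbols)    # symbol driving M_t is x_t
    relfull <- rbind(0L, rel)
    sym <- as.vector(t(symfull)[, times + 1, drop = FALSE])
    relv <- as.vector(t(relfull)[, times + 1, drop = FALSE])
  }
  ann <- data.frame(example = rep(seq_len(m), times = length(times)),
                    t = rep(times, each = m),
                    label = rep(b$labels, times = length(times)),
                    symbol = sym, rel_evidence = relv,
                    stringsAsFactors = FALSE)
  structure(list(X = X, ann = ann, which = which, m = m, times = times,
                 n = cfg$n, d = cfg$d, family = cfg$family),
            class = "mpn_states")
}

#' Principal-component model of a state population
#'
#' Centered PCA over the rows of a state matrix. Variance ratios are
#' normalized to sum to 1; each component's sign is fixed by making its
#' largest-magnitude loading positive, so repeated fits are reproducible
#' (angle-based analyses use absolute cosines and are sign-agnostic
#' anyway).
#'
#' @param states An `"mpn_states"` object or a numeric matrix
#'   (rows = observations).
#' @param rank Optional maximum number of components to retain.
#' @return An object of class `"mpn_pca"`: `center`, `rotation` (columns
#'   `w_alpha`, orthonormal), `var_ratio` (sums to 1 over the full
#'   spectrum), `sdev`, and `degenerate` (TRUE when the input had zero
#'   variance).
#' @export
fit_pca <- function(states, rank = NULL) {
  X <- if (inherits(states, "mpn_states")) states$X else states
  if (nrow(X) < 2) stop("need at least 2 rows for PCA", call. = FALSE)
  tot <- sum(apply(X, 2, stats::var))
  if (tot == 0) {
    w <- matrix(0, ncol(X), 1); w[1, 1] <- 1
    return(structure(list(center = colMeans(X), rotation = w, var_ratio = 1,
                          sdev = 0, degenerate = TRUE), class = "mpn_pca"))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE,
                      rank. = if (is.null(rank)) min(dim(X)) else rank)
  v <- pc$sdev^2
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(center = pc$center, rotation = rot,
                 var_ratio = v / sum(v), sdev = pc$sdev,
                 degenerate = FALSE),
            class = "mpn_pca")
}

#' Participation ratio
#'
#' Effective dimensionality of a variance spectrum:
#' `PR = (sum v)^2 / sum v^2`. Equals 1 when all variance is in one
#' component and `k` when it is spread evenly over `k`.
#'
#' @param v Nonnegative variance ratios (an `"mpn_pca"` object is also
#'   accepted).
#' @return The participation ratio.
#' @export
participation_ratio <- function(v) {
  if (inherits(v, "mpn_pca")) v <- v$var_ratio
  if (any(v < 0)) stop("variance ratios must be nonnegative", call. = FALSE)
  s <- sum(v)
  if (s == 0) stop("all-zero variance spectrum", call. = FALSE)
  s^2 / sum(v^2)
}

#' Variance explained by a task predictor
#'
#' Ordinary least-squares multi-output linear fit of the collected states
#' on a task predictor. The default report is the uniform average over
#' state features of the per-feature in-sample `r^2` (the convention of
#' the standard multi-output regression score); `method = "pooled"` gives
#' the variance-weighted alternative `1 - SSE_total / SST_total`.
#' Predictors: `"accumulated_evidence"` — the scalar running class-1
#' minus class-2 evidence count (inclusive of the current step);
#' `"present_input"` — indicator coding of the input symbol at each step
#' with the null input as reference.
#'
#' @param states An `"mpn_states"` object (or a matrix plus an `ann` data
#'   frame).
#' @param predictor `"accumulated_evidence"` or `"present_input"`.
#' @param ann Annotations when `states` is a bare matrix.
#' @param method `"uniform"` (default) or `"pooled"`.
#' @return `r^2` in `[0, 1]` (both methods are in-sample fits with an
#'   intercept, so neither can be negative).
#' @export
variance_explained <- function(states,
                               predictor = c("accumulated_evidence",
                                             "present_input"),
                               ann = NULL,
                               method = c("uniform", "pooled")) {
  predictor <- match.arg(predictor)
  method <- match.arg(method)
  if (inherits(states, "mpn_states")) {
    ann <- states$ann
    X <- states$X
  } else X <- states
  if (predictor == "accumulated_evidence") {
    design <- matrix(ann$rel_evidence, ncol = 1)
  } else {
    sym <- factor(ann$symbol)
    if (!"null" %in% levels(sym)) {
      stop("present-input coding needs a 'null' reference symbol",
           call. = FALSE)
    }
    sym <- stats::relevel(sym, ref = "null")
    design <- stats::model.matrix(~sym)[, -1, drop = FALSE]
  }
  if (all(apply(design, 2, stats::var) == 0)) {
    stop("constant predictor", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, design), X)
  res <- as.matrix(fit$residuals)
  sse_j <- colSums(res^2)
  sst_j <- colSums(sweep(X, 2, colMeans(X))^2)
  if (method == "pooled") return(1 - sum(sse_j) / sum(sst_j))
  ok <- sst_j > 0  # constant features carry no variance to explain
  mean(1 - sse_j[ok] / sst_j[ok])
}

# balanced class weights (inverse frequency), named by level
balanced_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * as.numeric(tab))
  stats::setNames(w, names(tab))
}

# linear max-margin decoder: fit on (X, y), return function predicting labels
fit_linear_decoder <- function(X, y) {
  y <- factor(y)
  lev <- levels(y)
  if (length(lev) == 2) {
    mod <- e1071::svm(X, y, kernel = "linear", scale = FALSE,
                      class.weights = balanced_weights(y))
    return(function(Xnew) as.character(stats::predict(mod, Xnew)))
  }
  # one-vs-rest with decision values; libsvm orients the decision value by
  # the order classes appear in the training data, so read the orientation
  # off the decision-value column name instead of assuming it
  mods <- lapply(lev, function(k) {
    yk <- factor(ifelse(y == k, "pos", "neg"), levels = c("pos", "neg"))
    e1071::svm(X, yk, kernel = "linear", scale = FALSE,
               class.weights = balanced_weights(yk))
  })
  function(Xnew) {
    dv <- vapply(mods, function(mdl) {
      m <- attr(stats::predict(mdl, Xnew, decision.values = TRUE),
                "decision.values")
      v <- as.numeric(m[, 1])
      if (startsWith(colnames(m)[1], "neg/")) v <- -v
      v
    }, numeric(nrow(Xnew)))
    lev[max.col(dv)]
  }
}

#' Cross-validated linear decoding accuracy
#'
#' Accuracy of a regularized linear max-margin classifier (balanced class
#' weights; one-vs-rest for three or more classes) under k-fold
#' cross-validation, averaged over folds.
#'
#' @param X State matrix (rows = examples).
#' @param labels Class labels, one per row.
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Optional seed for the fold assignment.
#' @return Mean held-out accuracy.
#' @export
decoding_accuracy <- function(X, labels, folds = 10, seed = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least two classes", call. = FALSE)
  if (min(table(labels)) < folds) {
    stop("need at least `folds` examples per class", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  fold_id <- sample(rep_len(seq_len(folds), nrow(X)))
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    dec <- fit_linear_decoder(X[tr, , drop = FALSE], labels[tr])
    mean(dec(X[!tr, , drop = FALSE]) == as.character(labels[!tr]))
  }, 0)
  mean(acc)
}

#' Cross-time decoding matrix
#'
#' Trains a decoder on the population state at one time step and evaluates
#' it at another, for every (train, test) pair, holding the example folds
#' fixed so train and test examples never overlap. The diagonal equals
#' same-time cross-validated decoding.
#'
#' @param states An `"mpn_states"` object with `"hidden"` states covering
#'   the requested times.
#' @param labels Per-example labels (defaults to the collected labels).
#' @param train_times,test_times Time steps (defaults: all collected).
#' @param folds Cross-validation folds (default 10).
#' @param seed Optional seed for the fold assignment.
#' @return A `length(train_times) x length(test_times)` accuracy matrix.
#' @export
cross_time_decoding <- function(states, labels = NULL, train_times = NULL,
                                test_times = NULL, folds = 10, seed = NULL) {
  stopifnot(inherits(states, "mpn_states"))
  if (is.null(train_times)) train_times <- states$times
  if (is.null(test_times)) test_times <- states$times
  m <- states$m
  if (is.null(labels)) labels <- states$ann$label[seq_len(m)]
  labels <- factor(labels)
  if (!is.null(seed)) set.seed(as.integer(seed))
  fold_id <- sample(rep_len(seq_len(folds), m))
  state_at <- function(t) {
    states$X[states$ann$t == t, , drop = FALSE]
  }
  acc <- matrix(NA_real_, length(train_times), length(test_times),
                dimnames = list(train_times, test_times))
  for (i in seq_along(train_times)) {
    Xtr_t <- state_at(train_times[i])
    decs <- lapply(seq_len(folds), function(f) {
      fit_linear_decoder(Xtr_t[fold_id != f, , drop = FALSE],
                         labels[fold_id != f])
    })
    for (j in seq_along(test_times)) {
      Xte_t <- state_at(test_times[j])
      accf <- vapply(seq_len(folds), function(f) {
        te <- fold_id == f
        mean(decs[[f]](Xte_t[te, , drop = FALSE]) ==
               as.character(labels[te]))
      }, 0)
      acc[i, j] <- mean(accf)
    }
  }
  acc
}

#' Readout alignment of input clusters
#'
#' Splits the hidden-activity population by the present input symbol, fits
#' a PCA per cluster, and reports the mean over readout vectors of the
#' absolute cosine between the readout and the cluster's top principal
#' direction, `|r . w1| / (|r| |w1|)` — high when the variation within a
#' cluster is what the readout reads.
#'
#' @param params An `"mpn_params"` (or `"mpn_fit"`).
#' @param states An `"mpn_states"` object of hidden activity with symbol
#'   annotations.
#' @return Named numeric vector of alignments, one per symbol cluster with
#'   at least two states.
#' @export
readout_alignment <- function(params, states) {
  if (inherits(params, "mpn_fit")) params <- params$params
  W <- params$W_RO
  syms <- unique(states$ann$symbol)
  out <- numeric(0)
  for (s in syms) {
    idx <- states$ann$symbol == s
    if (sum(idx) < 2) next
    pc <- fit_pca(states$X[idx, , drop = FALSE], rank = 1)
    if (pc$degenerate) next
    w1 <- pc$rotation[, 1]
    cosv <- abs(W %*% w1) / (sqrt(rowSums(W^2)) * sqrt(sum(w1^2)))
    out[s] <- mean(cosv)
  }
  out
}

#' Normalized state magnitude
#'
#' `|M|_F / sqrt(n d)` for modulation states, `|h|_2 / sqrt(n)` for hidden
#' states — the root-mean-square of the state's components, comparable
#' across families of different state sizes.
#'
#' @param state A modulation matrix / flattened modulation vector, or a
#'   hidden-state vector; also accepts a matrix of row-states (one value
#'   per row).
#' @param family `"mpn"` (default; normalize by `sqrt(n d)` = number of
#'   components) or `"rnn"`; both reduce to RMS over components, so the
#'   argument only documents intent.
#' @return The normalized magnitude (or vector of them).
#' @export
normalized_state_magnitude <- function(state, family = c("mpn", "rnn")) {
  family <- match.arg(family)
  if (is.matrix(state) && nrow(state) > 1 && ncol(state) > 1 &&
      family == "rnn") {
    return(sqrt(rowMeans(state^2)))
  }
  sqrt(mean(state^2))
}

#' Normalized time variability
#'
#' Per neuron and time step, the variance of the activity over a
#' `tau`-step rolling window divided by the window's mean squared
#' activity (population variance, so a zero-mean window scores exactly 1),
#' averaged over neurons and examples. Windows with zero energy are
#' excluded.
#'
#' @param H Hidden-activity array `n x T x B` (as returned by the compiled
#'   forward pass) or an `n x T` matrix for one example.
#' @param tau Rolling-window length (default 5).
#' @return A length-`T` series; entries for `t < tau` are `NA`.
#' @export
normalized_time_variability <- function(H, tau = 5) {
  if (is.matrix(H)) dim(H) <- c(dim(H), 1)
  n <- dim(H)[1]; Tn <- dim(H)[2]; B <- dim(H)[3]
  out <- rep(NA_real_, Tn)
  for (t in tau:Tn) {
    win <- H[, (t - tau + 1):t, , drop = FALSE]
    msq <- apply(win, c(1, 3), function(x) mean(x^2))
    mvar <- apply(win, c(1, 3), function(x) mean(x^2) - mean(x)^2)
    ok <- msq > 0
    if (any(ok)) out[t] <- mean(mvar[ok] / msq[ok])
  }
  out
}

#' Mean hidden activity
#'
#' `hbar_t = (1/n) sum_i |h_{i,t}|`, averaged over examples — the
#' population activity magnitude used to diagnose activity-silent delay
#' periods.
#'
#' @inheritParams normalized_time_variability
#' @return A length-`T` series.
#' @export
mean_hidden_activity <- function(H) {
  if (is.matrix(H)) dim(H) <- c(dim(H), 1)
  apply(abs(H), 2, mean)
}

#' Readout difference on the contextual task
#'
#' Applies the go-signal projection to every stored modulation state of a
#' contextual-task test set, passes the projected activity through the
#' readout (`y_GO = W_RO h_GO + b_RO`), groups the output sequences by
#' (subtask label, subtask, context) and forms, per subtask `tau` and
#' context `c`, the mean margin
#' `dy = (ybar_1;1 - ybar_2;1)/2 + (ybar_2;2 - ybar_1;2)/2` — positive
#' when the readouts separate that subtask's two classes at that time.
#'
#' @param fit An `"mpn_fit"` of an MPN trained on a context task.
#' @param m Test sequences (default 500).
#' @param seed Optional seed for the test draw.
#' @return Array `dy[t, tau, c]` with `t = 0..T` (state index), subtask
#'   `tau` in 1:2, context `c` in 1:2.
#' @export
readout_difference <- function(fit, m = 500, seed = NULL) {
  stopifnot(inherits(fit, "mpn_fit"),
            fit$task$mode %in% c("retro_context", "pro_context"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  b <- sample_batch(fit$task, fit$codebook, m)
  x_go <- fit$codebook$vectors[, "go"]
  fw <- forward_pass(fit$params, b$X, x_go = x_go)
  Tn <- fit$task$T
  W <- fit$params$W_RO; bro <- fit$params$b_RO
  dy <- array(NA_real_, c(Tn + 1, 2, 2),
              dimnames = list(t = 0:Tn, tau = 1:2, c = 1:2))
  # mean projected output per (label-of-subtask, tau, c): N x (T+1)
  ybar <- function(l, tau, cc) {
    idx <- which(b$labels_sub[, tau] == l & b$context == cc)
    if (length(idx) == 0) stop("empty group in readout_difference",
                               call. = FALSE)
    hg <- fw$Hgo[, , idx, drop = FALSE]          # n x (T+1) x |idx|
    hbar <- apply(hg, c(1, 2), mean)
    W %*% hbar + bro
  }
  for (tau in 1:2) for (cc in 1:2) {
    y1 <- ybar(1, tau, cc); y2 <- ybar(2, tau, cc)
    dy[, tau, cc] <- 0.5 * (y1[1, ] - y1[2, ]) + 0.5 * (y2[2, ] - y2[1, ])
  }
  dy
}

#' Attractor-angle shift between two fitted PCAs
#'
#' Angle in degrees between the top principal directions of two state
#' populations, `arccos(|w1 . w1'|)` — the absolute value removes the PCA
#' sign ambiguity. Used to quantify how much a line attractor reorients
#' (e.g. before vs after sequential learning).
#'
#' @param pca_before,pca_after `"mpn_pca"` objects on comparable
#'   populations.
#' @return Angle in degrees, in `[0, 90]`.
#' @export
attractor_angle_shift <- function(pca_before, pca_after) {
  if (pca_before$degenerate || pca_after$degenerate) {
    stop("degenerate principal components", call. = FALSE)
  }
  w1 <- pca_before$rotation[, 1]; w2 <- pca_after$rotation[, 1]
  cosv <- abs(sum(w1 * w2)) / (sqrt(sum(w1^2)) * sqrt(sum(w2^2)))
  acos(min(cosv, 1)) * 180 / pi
}
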