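#' Leading + sub-leading approximation of MPN hidden activity
#'
#' Analytical approximation built on the observation that modulation
#' effects are small relative to the unmodulated drive (Hadamard products
#' of two binary codewords scale as `1/d`): the hidden activity is the
#' feedforward response plus a history sum over single-modulation terms,
#' `hhat_t = phi(W x_t + b + eta * sum_{s=1}^{t-1} lam^(s-1)
#' phi(W x_{t-s} + b) .* (W (x_t .* x_{t-s})))`.
#' Exact at `t = 1`; the error decreases with growing `d` and `n`.
#'
#' @param params An `"mpn_params"` with the associative rule.
#' @param X `T x d` input matrix.
#' @param t Time step (1..T).
#' @return The approximate hidden activity `hhat_t` (length `n`).
#' @export
approx_hidden_mpn <- function(params, X, t) {
  cfg <- params$config
  stopifnot(cfg$family == "mpn", cfg$rule == "associative")
  if (t < 1 || t > nrow(X)) stop("t out of range", call. = FALSE)
  W <- params$W_inp; b <- params$b
  a <- drop(W %*% X[t, ]) + b
  if (t > 1) {
    acc <- 0
    for (s in 1:(t - 1)) {
      hs <- apply_act(drop(W %*% X[t - s, ]) + b, cfg$activation)
      acc <- acc + params$lam^(s - 1) *
        (hs * drop(W %*% (X[t, ] * X[t - s, ])))
    }
    a <- a + params$eta * acc
  }
  apply_act(a, cfg$activation)
}

#' Leading-order approximation of the MPN modulation state
#'
#' Replaces the exact hidden activity in the modulation update by its
#' feedforward approximation:
#' `Mhat_t = lam Mhat_{t-1} + eta phi(W x_t + b) x_t^T`, unrolled from
#' `Mhat_0 = 0`. Exact at `t = 1` and whenever `eta = 0`.
#'
#' @inheritParams approx_hidden_mpn
#' @param t Time step (0..T).
#' @return The approximate modulation matrix `Mhat_t` (`n x d`).
#' @export
approx_modulation_mpn <- function(params, X, t) {
  cfg <- params$config
  stopifnot(cfg$family == "mpn", cfg$rule == "associative")
  if (t < 0 || t > nrow(X)) stop("t out of range", call. = FALSE)
  W <- params$W_inp
  M <- matrix(0, cfg$n, cfg$d)
  if (t == 0) return(M)
  for (s in seq_len(t)) {
    h <- apply_act(drop(W %*% X[s, ]) + params$b, cfg$activation)
    M <- params$lam * M + params$eta * tcrossprod(h, X[s, ])
  }
  M
}

#' Exact closed-form MPNpre hidden activity
#'
#' For the presynaptic-only rule the modulation state does not depend on
#' hidden activity, so the hidden activity has an exact closed form in
#' terms of previous inputs:
#' `h_t = phi(W x_t + b + (eta/n) sum_{s=1}^{t-1} lam^(s-1)
#' W (x_t .* x_{t-s}))`. This is an identity with the recursion (not an
#' approximation) and serves as its independent oracle.
#'
#' @param params An `"mpn_params"` with the presynaptic rule and no
#'   modulation bound.
#' @inheritParams approx_hidden_mpn
#' @return The exact hidden activity `h_t` (length `n`).
#' @export
exact_hidden_mpnpre <- function(params, X, t) {
  cfg <- params$config
  stopifnot(cfg$family == "mpn", cfg$rule == "presynaptic")
  if (!is.null(cfg$m_b)) {
    stop("closed form is invalid under modulation bounds", call. = FALSE)
  }
  if (t < 1 || t > nrow(X)) stop("t out of range", call. = FALSE)
  W <- params$W_inp
  a <- drop(W %*% X[t, ]) + params$b
  if (t > 1) {
    acc <- 0
    for (s in 1:(t - 1)) {
      acc <- acc + params$lam^(s - 1) * drop(W %*% (X[t, ] * X[t - s, ]))
    }
    a <- a + (params$eta / cfg$n) * acc
  }
  apply_act(a, cfg$activation)
}

#' Closed-form MPNpre modulation state
#'
#' `M_t = (eta/n) sum_{s=0}^{t-1} lam^s 1 x_{t-s}^T` — exact identity with
#' the presynaptic recursion when no bound is active.
#'
#' @inheritParams exact_hidden_mpnpre
#' @return The modulation matrix `M_t` (`n x d`).
#' @export
closed_form_modulation_mpnpre <- function(params, X, t) {
  stopifnot(params$config$rule == "presynaptic")
  unrolled_modulation(params, X, t)
}

#' Relative approximation error
#'
#' `|approx - exact| / |exact|` in the vector 2-norm (Frobenius norm for
#' matrices). Zero-norm exact values are flagged as undefined.
#'
#' @param exact,approx Vectors or matrices of matching shape.
#' @return A nonnegative scalar (`NA` with a warning when `|exact| = 0`).
#' @export
approximation_error <- function(exact, approx) {
  if (length(exact) != length(approx)) {
    stop("shape mismatch in approximation_error", call. = FALSE)
  }
  den <- sqrt(sum(exact^2))
  if (den == 0) {
    warning("zero-norm exact value; relative error undefined")
    return(NA_real_)
  }
  sqrt(sum((approx - exact)^2)) / den
}

#' Mean approximation error over a test set
#'
#' Runs `m` fresh task sequences through the exact MPN recursion and the
#' analytical approximations, and reports the relative error of the
#' hidden-activity and modulation predictions averaged over sequences,
#' per time step and aggregated.
#'
#' @param params An associative-rule `"mpn_params"`.
#' @param task,codebook Task and codebook to draw test sequences from.
#' @param m Number of test sequences (default 50).
#' @param seed Optional seed.
#' @return A list with `per_t` (data frame `t`, `err_h`, `err_M`) and
#'   aggregate means `err_h`, `err_M`.
#' @export
approximation_error_profile <- function(params, task, codebook = NULL,
                                        m = 50, seed = NULL) {
  if (inherits(params, "mpn_fit")) {
    if (is.null(codebook)) codebook <- params$codebook
    params <- params$params
  }
  if (is.null(codebook)) codebook <- default_codebook(task)
  if (!is.null(seed)) set.seed(as.integer(seed))
  b <- sample_batch(task, codebook, m)
  Tn <- task$T
  eh <- matrix(NA_real_, Tn, m)
  em <- matrix(NA_real_, Tn, m)
  for (i in seq_len(m)) {
    X <- t(b$X[, , i])
    traj <- run_sequence(params, X, record = c("hidden", "state"))
    for (t in seq_len(Tn)) {
      eh[t, i] <- approximation_error(traj$hidden[t, ],
                                      approx_hidden_mpn(params, X, t))
      Mt <- matrix(traj$states[t + 1, ], params$config$n, params$config$d)
      em[t, i] <- approximation_error(Mt, approx_modulation_mpn(params, X, t))
    }
  }
  list(per_t = data.frame(t = seq_len(Tn),
                          err_h = rowMeans(eh), err_M = rowMeans(em)),
       err_h = mean(eh), err_M = mean(em))
}

#' Linearized RNN state
#'
#' Linear-expansion prediction of an RNN's hidden state about a slow point
#' under zero input: `hhat_t = sum_{s=1}^{t} J_rec^(t-s) J_inp x_s`
#' (assuming `h_0 = 0`). Exact for a linear-activation RNN; for trained
#' tanh RNNs the recurrent Jacobian's near-unit eigenvalues are the
#' integration modes.
#'
#' @param J_rec Recurrent Jacobian (`n x n`).
#' @param J_inp Input Jacobian (`n x d`).
#' @param X `T x d` input matrix.
#' @return `T x n` matrix of predicted states (row `t` is `hhat_t`).
#' @export
linearized_rnn_state <- function(J_rec, J_inp, X) {
  if (!is.matrix(J_rec) || nrow(J_rec) != ncol(J_rec)) {
    stop("J_rec must be square", call. = FALSE)
  }
  Tn <- nrow(X); n <- nrow(J_rec)
  H <- matrix(0, Tn, n)
  h <- numeric(n)
  for (t in seq_len(Tn)) {
    h <- drop(J_rec %*% h) + drop(J_inp %*% X[t, ])
    H[t, ] <- h
  }
  H
}

#' Eigenmode view of a linearized RNN
#'
#' Eigendecomposition of the recurrent Jacobian; modes with eigenvalues
#' near 1 act as integrators, modes with `|lambda| < 1` decay.
#'
#' @param J_rec Recurrent Jacobian.
#' @return `eigen()` decomposition (values sorted by decreasing modulus).
#' @export
rnn_linear_modes <- function(J_rec) {
  e <- eigen(J_rec)
  ord <- order(Mod(e$values), decreasing = TRUE)
  list(values = e$values[ord], vectors = e$vectors[, ord, drop = FALSE])
}

#' Locate a slow point of an RNN under constant input
#'
#' Minimizes `q(h) = |h - F(h, x)|^2` by quasi-Newton descent from `h0`,
#' where `F` is the network's step map. Used as the expansion point for
#' the linearization.
#'
#' @param params A `"vanilla_rnn"` or `"gru"` `"mpn_params"`.
#' @param x Constant input (default zero).
#' @param h0 Starting point (default zero).
#' @param tol Convergence tolerance on `q` (default 1e-8).
#' @return List with `h`, `q` (final objective), and `converged`.
#' @export
find_slow_point <- function(params, x = NULL, h0 = NULL, tol = 1e-8) {
  cfg <- params$config
  stopifnot(cfg$family %in% c("vanilla_rnn", "gru"))
  if (is.null(x)) x <- numeric(cfg$d)
  if (is.null(h0)) h0 <- numeric(cfg$n)
  stepf <- if (cfg$family == "vanilla_rnn") rnn_step else gru_step
  q <- function(h) sum((h - stepf(params, h, x))^2)
  opt <- stats::optim(h0, q, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  list(h = opt$par, q = opt$value, converged = opt$value < tol)
}
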