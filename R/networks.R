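#' Initialize network parameters
#'
#' Weight matrices are drawn with Xavier initialization — each element
#' uniform on `[-gamma, gamma]` with `gamma = sqrt(6 / (fan_in + fan_out))`.
#' For the MPN family the plasticity scalars are initialized as in the
#' training protocol: `eta ~ U[-3, 3]` and `lam = lambda_max`. All biases
#' start at zero.
#'
#' @param config An [model_config()] object.
#' @param seed Integer seed; initialization is deterministic given the seed.
#' @return An object of class `"mpn_params"`: a list of weight matrices /
#'   vectors plus the plasticity scalars, carrying the config as an
#'   attribute-like `$config` element.
#' @export
init_params <- function(config, seed) {
  stopifnot(inherits(config, "mpn_config"))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  set.seed(as.integer(seed))
  init_params_rng(config)
}

# Draw from the current RNG state (used when a caller manages seeding).
init_params_rng <- function(config) {
  n <- config$n; d <- config$d; N <- config$N
  xavier <- function(nr, nc) {
    g <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -g, g), nr, nc)
  }
  p <- list(W_inp = xavier(n, d), b = numeric(n))
  if (config$family == "mpn") {
    p$eta <- stats::runif(1, -3, 3)
    p$lam <- config$lambda_max
  } else if (config$family == "vanilla_rnn") {
    p$W_rec <- xavier(n, n)
  } else if (config$family == "gru") {
    p$W_rec_u <- xavier(n, n); p$W_inp_u <- xavier(n, d); p$b_u <- numeric(n)
    p$W_rec_r <- xavier(n, n); p$W_inp_r <- xavier(n, d); p$b_r <- numeric(n)
    p$W_rec <- xavier(n, n)
  }
  p$W_RO <- xavier(N, n)
  p$b_RO <- numeric(N)
  p$config <- config
  class(p) <- "mpn_params"
  p
}

#' @export
print.mpn_params <- function(x, ...) {
  print(x$config)
  cts <- count_trainable_params(x$config)
  cat(sprintf("  trainable entries: %d core + %d readout\n",
              cts$live_core, cts$live_readout))
  invisible(x)
}

# Names of the trainable parameter fields for a config.
trainable_names <- function(config) {
  nm <- "W_inp"
  if (config$hidden_bias) nm <- c(nm, "b")
  nm <- switch(config$family,
    feedforward = nm,
    mpn = c(nm, "eta", "lam"),
    vanilla_rnn = c(nm, "W_rec"),
    gru = c(nm, "W_rec_u", "W_inp_u", "b_u", "W_rec_r", "W_inp_r", "b_r",
            "W_rec"))
  nm <- c(nm, "W_RO")
  if (config$readout_bias) nm <- c(nm, "b_RO")
  nm
}

#' Count trainable parameters
#'
#' Core (non-readout) parameter counts follow the standard counting rule for
#' these architectures: feedforward `n(d+1)`; MPN / MPNpre `n(d+1) + 2` (the
#' two extra entries are the plasticity scalars `eta` and `lam`); Vanilla RNN
#' `n(n+d+1)`; GRU `3n(n+d+1)`; LSTM `4n(n+d+1)`. The readout layer
#' contributes `N(n+1)` with a bias and `Nn` without, identically for every
#' family, and is reported separately. These formulas count a hidden bias per
#' layer by convention; `live_core` / `live_readout` additionally report the
#' exact number of entries this package actually trains under the config's
#' bias flags.
#'
#' @param config An [model_config()] object, or a list with fields `family`,
#'   `n`, `d`, `N` (family may also be `"lstm"` for the formula count only).
#' @return A list with `core`, `readout` (formula counts) and `live_core`,
#'   `live_readout` (exact trainable-entry counts; `NA` for `"lstm"`, which
#'   this package does not instantiate).
#' @export
count_trainable_params <- function(config) {
  n <- config$n; d <- config$d; N <- config$N
  fam <- config$family
  core <- switch(fam,
    feedforward = n * (d + 1),
    mpn = n * (d + 1) + 2,
    vanilla_rnn = n * (n + d + 1),
    gru = 3 * n * (n + d + 1),
    lstm = 4 * n * (n + d + 1),
    stop("unknown family: ", fam, call. = FALSE))
  readout_bias <- isTRUE(config$readout_bias)
  readout <- if (readout_bias) N * (n + 1) else N * n
  if (fam == "lstm") {
    return(list(core = core, readout = readout,
                live_core = NA_integer_, live_readout = NA_integer_))
  }
  hb <- if (isTRUE(config$hidden_bias)) n else 0
  live_core <- switch(fam,
    feedforward = n * d + hb,
    mpn = n * d + hb + 2,
    vanilla_rnn = n * d + n * n + hb,
    gru = 3 * (n * d + n * n) + 2 * n + hb)  # gate biases always trained
  list(core = core, readout = readout,
       live_core = as.integer(live_core), live_readout = as.integer(readout))
}

#' Single MPN step (reference implementation)
#'
#' Applies the hidden-activity map and one synapse-modulation update. For the
#' multiplicative families the hidden activity is
#' `h_t = phi([(M_{t-1} + 1) .* W_inp] x_t + b)`; the additive variant uses
#' `h_t = phi((M_{t-1} + W_inp) x_t + b)`. The modulation update follows the
#' config's rule (see [model_config()]), then every element is clipped to
#' `[-m_b, m_b]` if a bound is set.
#'
#' This scalar-loop-free pure-R version is the package's reference oracle;
#' batched runs use the compiled path, which is tested to agree with it.
#'
#' @param params An `"mpn_params"` object of family `"mpn"` or
#'   `"feedforward"`.
#' @param M_prev The previous modulation state (`n x d`); use a zero matrix
#'   for the sequence start.
#' @param x A length-`d` input vector.
#' @return `list(h = <n-vector>, M = <n x d matrix>)`.
#' @export
mpn_step <- function(params, M_prev, x) {
  cfg <- params$config
  stopifnot(cfg$family %in% c("mpn", "feedforward"))
  W <- params$W_inp
  if (!is.matrix(M_prev) || any(dim(M_prev) != dim(W)) || length(x) != cfg$d) {
    stop("shape mismatch in mpn_step", call. = FALSE)
  }
  if (any(!is.finite(M_prev)) || any(!is.finite(x))) {
    stop("non-finite inputs in mpn_step", call. = FALSE)
  }
  eta <- if (cfg$family == "mpn") params$eta else 0
  lam <- if (cfg$family == "mpn") params$lam else 0
  a <- if (cfg$rule == "additive" && cfg$family == "mpn") {
    drop((M_prev + W) %*% x) + params$b
  } else {
    drop(((M_prev + 1) * W) %*% x) + params$b
  }
  h <- apply_act(a, cfg$activation)
  M <- switch(if (cfg$family == "mpn") cfg$rule else "associative",
    associative = ,
    additive = lam * M_prev + eta * tcrossprod(h, x),
    presynaptic = lam * M_prev + (eta / cfg$n) * matrix(x, cfg$n, cfg$d,
                                                        byrow = TRUE),
    postsynaptic = lam * M_prev + (eta / cfg$d) * matrix(h, cfg$n, cfg$d))
  if (!is.null(cfg$m_b)) M <- pmin(pmax(M, -cfg$m_b), cfg$m_b)
  list(h = h, M = M)
}

#' Single Vanilla RNN step (reference implementation)
#'
#' `h_t = phi(W_rec h_{t-1} + W_inp x_t + b)`.
#'
#' @inheritParams mpn_step
#' @param h_prev Previous hidden state (length `n`).
#' @return The new hidden state, a length-`n` vector.
#' @export
rnn_step <- function(params, h_prev, x) {
  cfg <- params$config
  stopifnot(cfg$family == "vanilla_rnn")
  if (length(h_prev) != cfg$n || length(x) != cfg$d) {
    stop("shape mismatch in rnn_step", call. = FALSE)
  }
  apply_act(drop(params$W_rec %*% h_prev + params$W_inp %*% x) + params$b,
            cfg$activation)
}

#' Single GRU step (reference implementation)
#'
#' Update gate `u_t`, reset gate `r_t`, candidate `hhat_t`, then
#' `h_t = (1 - u_t) * hhat_t + u_t * h_{t-1}`.
#'
#' @inheritParams rnn_step
#' @return The new hidden state, a length-`n` vector.
#' @export
gru_step <- function(params, h_prev, x) {
  cfg <- params$config
  stopifnot(cfg$family == "gru")
  if (length(h_prev) != cfg$n || length(x) != cfg$d) {
    stop("shape mismatch in gru_step", call. = FALSE)
  }
  sig <- function(a) 1 / (1 + exp(-a))
  u <- sig(drop(params$W_rec_u %*% h_prev + params$W_inp_u %*% x) + params$b_u)
  r <- sig(drop(params$W_rec_r %*% h_prev + params$W_inp_r %*% x) + params$b_r)
  hc <- apply_act(drop(params$W_rec %*% (h_prev * r) + params$W_inp %*% x) +
                    params$b, cfg$activation)
  (1 - u) * hc + u * h_prev
}

#' Readout layer
#'
#' `y = W_RO h + b_RO`; the classification label is the index of the maximal
#' output component.
#'
#' @inheritParams mpn_step
#' @param h A hidden-activity vector (length `n`) or an `n x m` matrix of
#'   column vectors.
#' @return Output vector / `N x m` matrix.
#' @export
readout <- function(params, h) {
  if (is.matrix(h)) params$W_RO %*% h + params$b_RO
  else drop(params$W_RO %*% h) + params$b_RO
}

#' Run a full input sequence
#'
#' Unrolls the family's step operation over a `T`-step input matrix from the
#' zero initial state and records the requested fields. The final output is
#' computed from `h_T`; for the MPN this means the classification depends on
#' `M_{T-1}` (the last state that feeds a hidden activity), which is why all
#' final-state analyses in this package use `M_{T-1}`.
#'
#' @inheritParams mpn_step
#' @param X A `T x d` input matrix (one row per time step).
#' @param record Character subset of `c("hidden", "state", "output")`:
#'   record per-step hidden activity, per-step states (`M_t` for the MPN
#'   including `M_0`; `h_t` for RNNs), per-step outputs.
#' @return An object of class `"mpn_trajectory"`: list with `inputs`, `y`
#'   (final output), `label` (argmax of `y`), and the recorded `hidden`
#'   (`T x n`), `states` (`(T+1) x (n d)` flattened for the MPN, `T x n`
#'   for RNNs), `outputs` (`T x N`).
#' @export
run_sequence <- function(params, X,
                         record = c("hidden", "state", "output")) {
  cfg <- params$config
  record <- match.arg(record, several.ok = TRUE)
  if (!is.matrix(X) || ncol(X) != cfg$d) {
    stop("X must be a T x d matrix", call. = FALSE)
  }
  Tn <- nrow(X)
  is_mpn <- cfg$family %in% c("mpn", "feedforward")
  hid <- if ("hidden" %in% record) matrix(NA_real_, Tn, cfg$n)
  out <- if ("output" %in% record) matrix(NA_real_, Tn, cfg$N)
  states <- if ("state" %in% record) {
    if (is_mpn) matrix(NA_real_, Tn + 1, cfg$n * cfg$d)
    else matrix(NA_real_, Tn, cfg$n)
  }
  M <- matrix(0, cfg$n, cfg$d)
  h <- numeric(cfg$n)
  if (is_mpn && "state" %in% record) states[1, ] <- as.vector(M)
  for (t in seq_len(Tn)) {
    x <- X[t, ]
    if (is_mpn) {
      st <- mpn_step(params, M, x)
      h <- st$h; M <- st$M
      if ("state" %in% record) states[t + 1, ] <- as.vector(M)
    } else {
      h <- if (cfg$family == "vanilla_rnn") rnn_step(params, h, x)
           else gru_step(params, h, x)
      if ("state" %in% record) states[t, ] <- h
    }
    if (any(!is.finite(h))) {
      stop("non-finite hidden activation at step ", t, call. = FALSE)
    }
    if ("hidden" %in% record) hid[t, ] <- h
    if ("output" %in% record) out[t, ] <- readout(params, h)
  }
  y <- readout(params, h)
  structure(list(inputs = X, y = y, label = which.max(y),
                 hidden = hid, states = states, outputs = out,
                 family = cfg$family),
            class = "mpn_trajectory")
}

#' Go-signal projection
#'
#' Maps a stored modulation state to the hidden activity the network would
#' produce if the go input arrived now:
#' `h_GO(M) = phi((M .* W_inp) x_go + W_inp x_go + b)`. With `M = M_{T-1}`
#' and the noiseless go vector this equals the network's actual `h_T` on a
#' noiseless sequence.
#'
#' @inheritParams mpn_step
#' @param M A modulation state (`n x d`), or a matrix whose columns are
#'   flattened states (`(n d) x m`) to project many states at once.
#' @param x_go The go-signal input vector (length `d`).
#' @return A length-`n` hidden activity (or `n x m` matrix).
#' @export
go_signal_projection <- function(params, M, x_go) {
  cfg <- params$config
  stopifnot(cfg$family %in% c("mpn", "feedforward"))
  if (length(x_go) != cfg$d) stop("x_go has wrong length", call. = FALSE)
  W <- params$W_inp
  proj1 <- function(Mm) {
    a <- if (cfg$rule == "additive" && cfg$family == "mpn") {
      drop((Mm + W) %*% x_go) + params$b
    } else {
      drop((Mm * W) %*% x_go + W %*% x_go) + params$b
    }
    apply_act(a, cfg$activation)
  }
  if (is.matrix(M) && nrow(M) == cfg$n * cfg$d) {
    apply(M, 2, function(v) proj1(matrix(v, cfg$n, cfg$d)))
  } else {
    proj1(M)
  }
}

#' Unrolled modulation state (closed form)
#'
#' For the associative rule the recursion `M_t = lam M_{t-1} + eta h_t x_t^T`
#' with `M_0 = 0` unrolls to `M_t = eta * sum_{s=0}^{t-1} lam^s h_{t-s}
#' x_{t-s}^T` (hidden activities taken from the exact recursion); for the
#' presynaptic rule `M_t = (eta/n) sum_{s=0}^{t-1} lam^s 1 x_{t-s}^T`. These
#' closed forms are exact identities with the recursion and serve as
#' independent oracles for it; they are invalid under modulation bounds,
#' where clipping breaks linearity.
#'
#' @inheritParams run_sequence
#' @param t Time index (1..T) at which to evaluate `M_t`.
#' @return The `n x d` modulation state `M_t`.
#' @export
unrolled_modulation <- function(params, X, t) {
  cfg <- params$config
  stopifnot(cfg$family == "mpn",
            cfg$rule %in% c("associative", "presynaptic"))
  if (!is.null(cfg$m_b)) {
    stop("closed form is invalid under modulation bounds", call. = FALSE)
  }
  if (t < 1 || t > nrow(X)) stop("t out of range", call. = FALSE)
  n <- cfg$n; d <- cfg$d
  M <- matrix(0, n, d)
  if (cfg$rule == "presynaptic") {
    for (s in 0:(t - 1)) {
      M <- M + (params$eta / n) * params$lam^s *
        matrix(X[t - s, ], n, d, byrow = TRUE)
    }
    return(M)
  }
  # associative: need the exact hidden activities
  traj <- run_sequence(params, X[seq_len(t), , drop = FALSE], record = "hidden")
  for (s in 0:(t - 1)) {
    M <- M + params$eta * params$lam^s *
      tcrossprod(traj$hidden[t - s, ], X[t - s, ])
  }
  M
}
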