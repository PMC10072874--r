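#' Input codebook of random binary vectors
#'
#' Every task symbol (evidence classes, null, go, context cues, ...) maps
#' one-to-one to a fixed random binary vector whose elements are drawn
#' independently and uniformly from `{0, sqrt(2/d)}`. Under this scheme a
#' codeword has expected squared magnitude 1, two independent codewords have
#' expected dot product 1/2, and their Hadamard product has expected squared
#' magnitude 1/d — the scaling that makes modulation effects subleading and
#' the analytical approximations work.
#'
#' @param symbols Character vector of distinct symbol names.
#' @param d Input dimension.
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @param active Optional named list mapping a symbol to the indices of its
#'   active dimensions (used by the contextual task, whose two subtask
#'   streams occupy complementary halves of the input); elements outside
#'   the active set are zero.
#' @return An object of class `"mpn_codebook"` with a `d x K` matrix
#'   `$vectors` (columns named by symbol).
#' @export
make_codebook <- function(symbols, d, seed = NULL, active = NULL) {
  if (anyDuplicated(symbols)) stop("duplicate symbols", call. = FALSE)
  if (d < 1) stop("d must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  v <- sqrt(2 / d)
  vecs <- matrix(v * (stats::runif(d * length(symbols)) < 0.5),
                 d, length(symbols), dimnames = list(NULL, symbols))
  if (!is.null(active)) {
    for (s in names(active)) {
      keep <- active[[s]]
      vecs[setdiff(seq_len(d), keep), s] <- 0
    }
  }
  structure(list(vectors = vecs, d = d, symbols = symbols),
            class = "mpn_codebook")
}

#' Integration task specification
#'
#' Defines one generative integration task. A sequence has `T` steps: a
#' stimulus period, an optional delay period (zero input apart from noise),
#' and a final go-signal step. Isotropic Gaussian noise with per-element sd
#' `noise_mag / sqrt(d)` — i.e. expected squared vector magnitude
#' `noise_mag^2` — is added to every step, including delay and go.
#'
#' @param mode `"simple"` (optionally with delay), `"retro_context"`,
#'   `"pro_context"`, `"continuous"`, or `"true_anti"`.
#' @param N Number of evidence classes (2 for the context / continuous /
#'   true-anti modes).
#' @param T Sequence length (includes the go step).
#' @param T_delay Delay steps between the last stimulus and the go signal
#'   (simple mode); must satisfy `T_delay < T - 1`.
#' @param d Input dimension (must be even for the context modes, whose two
#'   subtask streams each occupy `d/2` dimensions).
#' @param noise_mag Expected input-noise vector magnitude (default 0.1, a
#'   signal-to-noise ratio of 10 against unit-magnitude codewords).
#' @param T_context,ctx_pre_delay,ctx_post_delay Context window layout for
#'   the context modes; the defaults give the 19 stimulus + 10 delay +
#'   5 context + 5 delay + 1 go layout at `T = 40` (mirrored for the
#'   prospective variant).
#' @param mu_range Continuous mode: the sequence mean is drawn uniformly
#'   from `[-mu_range, mu_range]` (default 0.1875) and the per-step signal
#'   from `Normal(mu, var = T/750)`.
#' @param delay_input_mag Magnitude of a dedicated delay codeword passed
#'   during delay steps (default 0: delay input is pure noise).
#' @return An object of class `"mpn_task"`; `$T_stim` gives the derived
#'   number of stimulus steps.
#' @export
task_spec <- function(mode = c("simple", "retro_context", "pro_context",
                               "continuous", "true_anti"),
                      N = 2, T = 20, T_delay = 0, d = 50, noise_mag = 0.1,
                      T_context = 5, ctx_pre_delay = 10, ctx_post_delay = 5,
                      mu_range = 0.1875, delay_input_mag = 0) {
  mode <- match.arg(mode)
  if (mode %in% c("retro_context", "pro_context")) {
    if (d %% 2 != 0) stop("context modes need even d", call. = FALSE)
    N <- 2L
    T_stim <- T - 1L - ctx_pre_delay - T_context - ctx_post_delay
    if (T_stim < 1) stop("context layout does not fit in T", call. = FALSE)
  } else if (mode %in% c("continuous", "true_anti")) {
    N <- 2L
    if (T_delay >= T - 1) stop("T_delay must be < T - 1", call. = FALSE)
    T_stim <- T - 1L - T_delay
  } else {
    if (T_delay >= T - 1) stop("T_delay must be < T - 1", call. = FALSE)
    T_stim <- T - 1L - T_delay
  }
  structure(list(mode = mode, N = as.integer(N), T = as.integer(T),
                 T_delay = as.integer(T_delay), T_stim = as.integer(T_stim),
                 d = as.integer(d), noise_mag = noise_mag,
                 T_context = as.integer(T_context),
                 ctx_pre_delay = as.integer(ctx_pre_delay),
                 ctx_post_delay = as.integer(ctx_post_delay),
                 mu_range = mu_range, delay_input_mag = delay_input_mag),
            class = "mpn_task")
}

#' Default codebook for a task
#'
#' Builds the codebook whose symbols the task's generator draws from:
#' `evid1..evidN`, `null`, `go` for the discrete modes (plus `delay` when a
#' nonzero delay input is configured, `true`/`anti` cues for the true-anti
#' mode), `sig` and `go` for the continuous mode, and per-stream evidence /
#' null symbols on complementary halves plus full-width `go`, `ctx1`,
#' `ctx2` for the context modes.
#'
#' @inheritParams make_codebook
#' @param spec An [task_spec()] object.
#' @return An `"mpn_codebook"`.
#' @export
default_codebook <- function(spec, seed = NULL) {
  d <- spec$d
  if (spec$mode %in% c("retro_context", "pro_context")) {
    half1 <- seq_len(d / 2)
    half2 <- setdiff(seq_len(d), half1)
    syms <- c(paste0("s1_", c(paste0("evid", 1:2), "null")),
              paste0("s2_", c(paste0("evid", 1:2), "null")),
              "go", "ctx1", "ctx2")
    active <- c(stats::setNames(rep(list(half1), 3), syms[1:3]),
                stats::setNames(rep(list(half2), 3), syms[4:6]))
    return(make_codebook(syms, d, seed = seed, active = active))
  }
  if (spec$mode == "continuous") {
    return(make_codebook(c("sig", "go"), d, seed = seed))
  }
  syms <- c(paste0("evid", seq_len(spec$N)), "null", "go")
  if (spec$mode == "true_anti") syms <- c(syms, "true", "anti")
  if (spec$delay_input_mag > 0) syms <- c(syms, "delay")
  make_codebook(syms, d, seed = seed)
}

# ---- evidence-vector sampling -------------------------------------------

# enumerate all evidence vectors a in N^N with sum(a) <= T_stim and a unique
# maximum; rows of the returned matrix
enumerate_evidence <- function(N, T_stim) {
  recurse <- function(k, rem) {
    if (k == 1) return(matrix(0:rem, ncol = 1))
    parts <- lapply(0:rem, function(v) {
      cbind(v, recurse(k - 1, rem - v), deparse.level = 0)
    })
    do.call(rbind, parts)
  }
  ev <- recurse(N, T_stim)
  mx <- apply(ev, 1, max)
  nmax <- rowSums(ev == mx)
  ev[nmax == 1, , drop = FALSE]
}

# number of weak compositions of N parts with sum <= Tm
n_compositions <- function(N, Tm) if (Tm < 0) 0 else choose(Tm + N, N)

# unrank index k (0-based) into the lexicographic weak composition of N
# parts with sum <= Tm (stars-and-bars with a slack part)
unrank_composition <- function(k, N, Tm) {
  a <- integer(N)
  rem <- Tm
  for (j in seq_len(N)) {
    v <- 0
    repeat {
      # completions with a_j = v: compositions of the remaining N - j parts
      # (plus slack) with sum <= rem - v
      cnt <- n_compositions(N - j, rem - v)
      if (k < cnt) break
      k <- k - cnt
      v <- v + 1
    }
    a[j] <- v
    rem <- rem - v
  }
  a
}

#' Sample evidence vectors
#'
#' Draws uniformly over the set of `N`-dimensional evidence vectors with
#' total evidence at most `T_stim` and a unique maximal entry (sequences
#' with tied maximal evidence are eliminated). Small supports are sampled
#' by exact enumeration; large ones by combinatorial unranking of
#' stars-and-bars compositions with tie rejection, which preserves exact
#' uniformity without materializing the support.
#'
#' @param N Number of classes (>= 2).
#' @param T_stim Number of stimulus steps (>= 1).
#' @param n Number of vectors to draw.
#' @param enum_cap Enumerate exactly when the composition count is at most
#'   this (default `1e6`).
#' @return An `n x N` integer matrix of evidence counts.
#' @export
sample_evidence_vector <- function(N, T_stim, n = 1, enum_cap = 1e6) {
  stopifnot(N >= 2, T_stim >= 1)
  if (n_compositions(N, T_stim) <= enum_cap) {
    supp <- evidence_support(N, T_stim)
    if (nrow(supp) == 0) stop("no valid evidence vector exists", call. = FALSE)
    return(supp[sample.int(nrow(supp), n, replace = TRUE), , drop = FALSE])
  }
  total <- n_compositions(N, T_stim)
  out <- matrix(0L, n, N)
  for (i in seq_len(n)) {
    repeat {
      k <- floor(stats::runif(1) * total)
      a <- unrank_composition(k, N, T_stim)
      mx <- max(a)
      if (sum(a == mx) == 1) break
    }
    out[i, ] <- a
  }
  out
}

# memoized enumeration
.evidence_cache <- new.env(parent = emptyenv())
evidence_support <- function(N, T_stim) {
  key <- paste(N, T_stim, sep = "_")
  if (is.null(.evidence_cache[[key]])) {
    .evidence_cache[[key]] <- enumerate_evidence(N, T_stim)
  }
  .evidence_cache[[key]]
}

# ---- sequence generation ------------------------------------------------

add_noise <- function(Xc, noise_mag, d) {
  if (noise_mag <= 0) return(Xc)
  Xc + stats::rnorm(length(Xc), sd = noise_mag / sqrt(d))
}

# symbols for the stimulus period of a simple-mode example
stimulus_symbols <- function(ev, T_stim) {
  syms <- c(rep(paste0("evid", seq_along(ev)), ev),
            rep("null", T_stim - sum(ev)))
  sample(syms)
}

#' Sample one task example
#'
#' Generates a single `SequenceExample` from the task's generative model:
#' evidence vector uniform over the valid set, symbol order uniform over
#' permutations, delay steps zero (before noise), go codeword last, noise
#' on every step. Dispatches on the task mode; see [task_spec()].
#'
#' @param spec An [task_spec()] object.
#' @param codebook An [make_codebook()] codebook containing the task's
#'   symbols (see [default_codebook()]).
#' @return A list with `X` (`T x d`, noise included), `X_clean`, `label`
#'   (1-based), `evidence` (counts, or the scalar mean for the continuous
#'   mode), `symbols` (per-step annotation), and mode-specific fields
#'   (`context`, `cue`).
#' @export
sample_sequence <- function(spec, codebook) {
  b <- sample_batch(spec, codebook, 1)
  ex <- list(X = t(b$X[, , 1]), X_clean = t(b$X_clean[, , 1]),
             label = b$labels[1],
             evidence = if (is.matrix(b$evidence)) b$evidence[, 1]
                        else b$evidence[1],
             symbols = b$symbols[, 1])
  if (!is.null(b$context)) ex$context <- b$context[1]
  if (!is.null(b$cue)) ex$cue <- b$cue[1]
  ex
}

#' Sample a batch of task examples
#'
#' Batched version of [sample_sequence()]; the workhorse behind training,
#' validation and state collection. Inputs are returned in the layout the
#' compiled forward/backward passes consume.
#'
#' @inheritParams sample_sequence
#' @param B Number of examples.
#' @return A list with arrays `X` and `X_clean` (`d x T x B`), integer
#'   `labels`, `evidence` (`N x B`, or length-`B` means for continuous
#'   mode), `symbols` (`T x B` character), and `context`/`cue` where
#'   applicable.
#' @export
sample_batch <- function(spec, codebook, B) {
  switch(spec$mode,
    simple = batch_simple(spec, codebook, B),
    true_anti = batch_true_anti(spec, codebook, B),
    continuous = batch_continuous(spec, codebook, B),
    retro_context = batch_context(spec, codebook, B, retro = TRUE),
    pro_context = batch_context(spec, codebook, B, retro = FALSE))
}

batch_simple <- function(spec, codebook, B) {
  d <- spec$d; Tn <- spec$T
  cb <- codebook$vectors
  ev <- sample_evidence_vector(spec$N, spec$T_stim, B)
  symbols <- matrix("", Tn, B)
  for (i in seq_len(B)) {
    symbols[seq_len(spec$T_stim), i] <- stimulus_symbols(ev[i, ], spec$T_stim)
  }
  if (spec$T_delay > 0) {
    symbols[spec$T_stim + seq_len(spec$T_delay), ] <- ".delay"
  }
  symbols[Tn, ] <- "go"
  Xc <- array(0, c(d, Tn, B))
  idx <- symbols != ".delay"
  Xc[rep(idx, each = d)] <- cb[, symbols[idx]]
  if (spec$T_delay > 0 && spec$delay_input_mag > 0) {
    dv <- spec$delay_input_mag * cb[, "delay"]
    Xc[array(rep(symbols == ".delay", each = d), c(d, Tn, B))] <-
      rep(dv, times = sum(symbols == ".delay"))
  }
  labels <- max.col(ev)  # ties impossible by construction
  list(X = add_noise(Xc, spec$noise_mag, d), X_clean = Xc,
       labels = as.integer(labels), evidence = t(ev), symbols = symbols)
}

batch_true_anti <- function(spec, codebook, B) {
  out <- batch_simple(spec, codebook, B)
  cb <- codebook$vectors
  cue <- sample(c("true", "anti"), B, replace = TRUE)
  stim <- seq_len(spec$T_stim)
  for (i in seq_len(B)) {
    out$X_clean[, stim, i] <- out$X_clean[, stim, i] + cb[, cue[i]]
    if (cue[i] == "anti") out$labels[i] <- 3L - out$labels[i]  # argmin, N = 2
  }
  out$X <- add_noise(out$X_clean, spec$noise_mag, spec$d)
  out$cue <- cue
  out
}

batch_continuous <- function(spec, codebook, B) {
  d <- spec$d; Tn <- spec$T
  cb <- codebook$vectors
  mu <- stats::runif(B, -spec$mu_range, spec$mu_range)
  while (any(mu == 0)) mu[mu == 0] <- stats::runif(sum(mu == 0),
                                                   -spec$mu_range,
                                                   spec$mu_range)
  s <- matrix(stats::rnorm((Tn - 1) * B, mean = rep(mu, each = Tn - 1),
                           sd = sqrt(Tn / 750)), Tn - 1, B)
  Xc <- array(0, c(d, Tn, B))
  sig <- cb[, "sig"]
  for (i in seq_len(B)) {
    Xc[, seq_len(Tn - 1), i] <- outer(sig, s[, i])
    Xc[, Tn, i] <- cb[, "go"]
  }
  labels <- ifelse(mu > 0, 1L, 2L)
  symbols <- matrix("sig", Tn, B)
  symbols[Tn, ] <- "go"
  list(X = add_noise(Xc, spec$noise_mag, d), X_clean = Xc,
       labels = labels, evidence = mu, symbols = symbols, signal = s)
}

batch_context <- function(spec, codebook, B, retro = TRUE) {
  d <- spec$d; Tn <- spec$T
  cb <- codebook$vectors
  Ts <- spec$T_stim
  # step layout
  if (retro) {
    stim <- seq_len(Ts)
    ctx <- Ts + spec$ctx_pre_delay + seq_len(spec$T_context)
  } else {
    ctx <- spec$ctx_pre_delay + seq_len(spec$T_context)
    stim <- spec$ctx_pre_delay + spec$T_context + spec$ctx_post_delay +
      seq_len(Ts)
  }
  ev1 <- sample_evidence_vector(2, Ts, B)
  ev2 <- sample_evidence_vector(2, Ts, B)
  context <- sample(1:2, B, replace = TRUE)
  Xc <- array(0, c(d, Tn, B))
  symbols <- matrix(".delay", Tn, B)
  symbols[Tn, ] <- "go"
  sym1 <- matrix("", Ts, B); sym2 <- matrix("", Ts, B)
  for (i in seq_len(B)) {
    s1 <- paste0("s1_", sub("evid", "evid", stimulus_symbols(ev1[i, ], Ts)))
    s2 <- paste0("s2_", stimulus_symbols(ev2[i, ], Ts))
    sym1[, i] <- s1; sym2[, i] <- s2
    Xc[, stim, i] <- cb[, s1] + cb[, s2]
    Xc[, ctx, i] <- cb[, paste0("ctx", context[i])]
    Xc[, Tn, i] <- cb[, "go"]
    symbols[stim, i] <- paste(s1, s2, sep = "+")
    symbols[ctx, i] <- paste0("ctx", context[i])
  }
  lab1 <- max.col(ev1); lab2 <- max.col(ev2)
  labels <- ifelse(context == 1, lab1, lab2)
  list(X = add_noise(Xc, spec$noise_mag, d), X_clean = Xc,
       labels = as.integer(labels),
       evidence = rbind(t(ev1), t(ev2)), symbols = symbols,
       context = context, labels_sub = cbind(lab1, lab2))
}

#' Random input projection for external task streams
#'
#' Low-dimensional external task streams (e.g. from standard neuroscience
#' task batteries) are passed through a fixed random affine map
#' `x = W_rand x' + b_rand` so that delay periods with zero external input
#' still drive the network. The map is drawn once with Xavier
#' initialization and frozen.
#'
#' @param d Output (network input) dimension.
#' @param d_ext External stream dimension.
#' @param seed Optional integer seed.
#' @return A list with `W_rand` (`d x d_ext`) and `b_rand` (length `d`).
#' @export
make_input_projection <- function(d, d_ext, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- sqrt(6 / (d + d_ext))
  list(W_rand = matrix(stats::runif(d * d_ext, -g, g), d, d_ext),
       b_rand = stats::runif(d, -g, g))
}

#' @rdname make_input_projection
#' @param proj A projection from `make_input_projection()`.
#' @param x_ext A length-`d_ext` vector or `d_ext x T` matrix of external
#'   inputs.
#' @return The projected input(s).
#' @export
random_input_projection <- function(proj, x_ext) {
  if (is.matrix(x_ext)) proj$W_rand %*% x_ext + proj$b_rand
  else drop(proj$W_rand %*% x_ext) + proj$b_rand
}
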