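#' Model configuration
#'
#' Describes one network from the families studied in this package: the
#' multi-plasticity network (MPN) — a two-layer feedforward network whose
#' input weights are multiplicatively modulated by a fast, exponentially
#' decaying synapse-modulation (SM) matrix — its variants (presynaptic-only,
#' postsynaptic-only, additive), the plain feedforward network, and the
#' recurrent baselines (Vanilla RNN, GRU).
#'
#' @param family One of `"feedforward"`, `"mpn"`, `"vanilla_rnn"`, `"gru"`.
#' @param d Input layer size (number of input neurons).
#' @param n Hidden layer size.
#' @param N Output layer size (number of task classes).
#' @param rule Modulation rule for `family = "mpn"`: `"associative"`
#'   (increment `eta * h x^T`, pre- and postsynaptic dependent),
#'   `"presynaptic"` (`eta/n * 1 x^T`), `"postsynaptic"` (`eta/d * h 1^T`),
#'   or `"additive"` (associative update, but the SM matrix adds to the
#'   input weights instead of multiplying them).
#' @param activation `"tanh"` (default) or `"relu"`.
#' @param lambda_max Ceiling on the modulation decay factor, in (0, 1).
#'   The learned decay `lam` is kept in `[0, lambda_max]` throughout
#'   training; default 0.95.
#' @param m_b Optional positive modulation bound: every element of the SM
#'   matrix is clipped to `[-m_b, m_b]` after each update. `NULL` (default)
#'   leaves modulations unbounded.
#' @param hidden_bias,readout_bias Train a hidden-layer / readout bias?
#'   `hidden_bias` defaults to `FALSE` (bias fixed at zero) for the MPN and
#'   feedforward families and to `TRUE` for the recurrent baselines, whose
#'   standard parameterization keeps them (the GRU's gate biases are always
#'   trainable). `readout_bias` defaults to `FALSE`.
#'
#' @return An object of class `"mpn_config"`.
#' @seealso [init_params()], [count_trainable_params()]
#' @export
model_config <- function(family = c("mpn", "feedforward", "vanilla_rnn", "gru"),
                         d, n, N,
                         rule = c("associative", "presynaptic",
                                  "postsynaptic", "additive"),
                         activation = c("tanh", "relu"),
                         lambda_max = 0.95, m_b = NULL,
                         hidden_bias = NULL, readout_bias = FALSE) {
  family <- match.arg(family)
  if (is.null(hidden_bias)) {
    hidden_bias <- family %in% c("vanilla_rnn", "gru")
  }
  rule <- match.arg(rule)
  activation <- match.arg(activation)
  if (!is.numeric(d) || !is.numeric(n) || !is.numeric(N) ||
      d < 1 || n < 1 || N < 1 ||
      d != round(d) || n != round(n) || N != round(N)) {
    stop("d, n and N must be integers >= 1", call. = FALSE)
  }
  if (!is.numeric(lambda_max) || lambda_max <= 0 || lambda_max >= 1) {
    stop("lambda_max must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(m_b) && (!is.numeric(m_b) || m_b <= 0)) {
    stop("m_b must be a positive scalar (or NULL)", call. = FALSE)
  }
  structure(
    list(family = family, rule = rule,
         d = as.integer(d), n = as.integer(n), N = as.integer(N),
         activation = activation, lambda_max = lambda_max, m_b = m_b,
         hidden_bias = isTRUE(hidden_bias), readout_bias = isTRUE(readout_bias)),
    class = "mpn_config")
}

#' @export
print.mpn_config <- function(x, ...) {
  fam <- if (x$family == "mpn") paste0("mpn (", x$rule, ")") else x$family
  cat(sprintf("<mpn_config> %s  d=%d n=%d N=%d  act=%s lambda_max=%g%s\n",
              fam, x$d, x$n, x$N, x$activation, x$lambda_max,
              if (is.null(x$m_b)) "" else sprintf(" m_b=%g", x$m_b)))
  invisible(x)
}

act_code <- function(activation) if (activation == "tanh") 0L else 1L

rule_code <- function(rule) {
  c(associative = 0L, presynaptic = 1L, postsynaptic = 2L, additive = 3L)[[rule]]
}

apply_act <- function(a, activation) {
  if (activation == "tanh") tanh(a) else pmax(a, 0)
}
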