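# Shared fixtures. Heavy trained models are memoized so the acceptance
# blocks and the qualitative-dynamics blocks reuse the same fits within a
# test run.

.model_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.model_cache[[key]])) .model_cache[[key]] <- builder()
  .model_cache[[key]]
}

# paper-scale two-class integration task
std_task <- function() task_spec("simple", N = 2, T = 20, d = 50)

std_mpn_fit <- function(seed) {
  cached(paste0("mpn_std_", seed), function() {
    train(model_config("mpn", d = 50, n = 100, N = 2), std_task(),
          train_config(), seed = seed)
  })
}

std_rnn_fit <- function(seed) {
  cached(paste0("rnn_std_", seed), function() {
    train(model_config("vanilla_rnn", d = 50, n = 100, N = 2), std_task(),
          train_config(), seed = seed)
  })
}

std_gru_fit <- function(seed) {
  cached(paste0("gru_std_", seed), function() {
    train(model_config("gru", d = 50, n = 100, N = 2), std_task(),
          train_config(), seed = seed)
  })
}

std_hidden_states <- function(fit, seed) {
  cached(paste0("st_", fit$config$family, fit$config$rule, fit$seed, seed),
         function() collect_states(fit, m = 1000, which = "hidden",
                                   seed = seed))
}

# tiny config for mechanics tests
micro_config <- function(family = "mpn", ...) {
  model_config(family, d = 10, n = 8, N = 2, ...)
}

micro_task <- function(...) task_spec("simple", N = 2, T = 8, d = 10, ...)

micro_tc <- function(...) {
  args <- list(batch_size = 8, validation_size = 50, min_batches = 0,
               max_batches = 60, stop_rule = "max")
  over <- list(...)
  args[names(over)] <- over
  do.call(train_config, args)
}

# random T x d input matrix
rand_X <- function(T, d, scale = 0.5) matrix(stats::rnorm(T * d, sd = scale), T, d)
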