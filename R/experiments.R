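# Experiment grids: each sweep trains fresh networks per (condition, seed)
# cell and returns a tidy per-seed table. Defaults are desk-scale; pass a
# custom train_config / grids to change problem sizes.

train_eval <- function(config, task, tc, seed, n_test = 1000,
                       codebook = NULL) {
  fit <- train(config, task, tc, seed = seed, codebook = codebook)
  acc <- evaluate_accuracy(fit, n_examples = n_test, seed = seed + 7L)
  list(fit = fit, acc = acc)
}

family_config <- function(family, d, n, N, ...) {
  switch(family,
    mpn = model_config("mpn", d = d, n = n, N = N, ...),
    mpnpre = model_config("mpn", rule = "presynaptic", d = d, n = n, N = N,
                          ...),
    mpnpost = model_config("mpn", rule = "postsynaptic", d = d, n = n,
                           N = N, ...),
    mpn_additive = model_config("mpn", rule = "additive", d = d, n = n,
                                N = N, ...),
    vanilla_rnn = model_config("vanilla_rnn", d = d, n = n, N = N, ...),
    gru = model_config("gru", d = d, n = n, N = N, ...),
    stop("unknown family label: ", family, call. = FALSE))
}

#' Capacity sweep: accuracy vs number of classes
#'
#' Trains small networks (`d = 10`, `n = 3` by default) on N-class
#' integration at fixed `T` and reports per-seed accuracy with the
#' analytic chance level `1/N`. The MPN is additionally run at `d = 40`,
#' where its parameter count is comparable to the `d = 10` GRU.
#'
#' @param families Character vector of family labels (`"mpn"`,
#'   `"mpnpre"`, `"mpnpost"`, `"mpn_additive"`, `"vanilla_rnn"`, `"gru"`).
#' @param N_values Class counts to sweep.
#' @param seeds Seeds (one network per family x N x seed).
#' @param d,n,T Task / network geometry.
#' @param tc A [train_config()]; default: loss-plateau stopping.
#' @param n_test Fresh test examples per cell.
#' @param mpn_d40 Also run the MPN at `d = 40`?
#' @return Data frame with columns `family`, `N`, `d`, `seed`, `accuracy`,
#'   `chance`, `batches`.
#' @export
sweep_capacity <- function(families = c("mpn", "mpnpre", "vanilla_rnn", "gru"),
                           N_values = 2:5, seeds = 1:5, d = 10, n = 3,
                           T = 20, tc = NULL, n_test = 1000,
                           mpn_d40 = TRUE) {
  if (is.null(tc)) tc <- train_config(stop_rule = "plateau")
  cells <- expand.grid(family = families, N = N_values, d = d,
                       stringsAsFactors = FALSE)
  if (mpn_d40 && "mpn" %in% families) {
    cells <- rbind(cells, expand.grid(family = "mpn", N = N_values, d = 40,
                                      stringsAsFactors = FALSE))
  }
  out <- list()
  for (i in seq_len(nrow(cells))) {
    for (s in seeds) {
      cfg <- family_config(cells$family[i], d = cells$d[i], n = n,
                           N = cells$N[i])
      task <- task_spec("simple", N = cells$N[i], T = T, d = cells$d[i])
      r <- train_eval(cfg, task, tc, seed = s, n_test = n_test)
      out[[length(out) + 1]] <- data.frame(
        family = cells$family[i], N = cells$N[i], d = cells$d[i], seed = s,
        accuracy = r$acc, chance = 1 / cells$N[i], batches = r$fit$batches)
    }
  }
  do.call(rbind, out)
}

#' Sequence-length sweep: accuracy vs T
#'
#' @inheritParams sweep_capacity
#' @param T_values Sequence lengths to sweep (N = 2 throughout).
#' @return Data frame with per-seed accuracies.
#' @export
sweep_sequence_length <- function(families = c("mpn", "mpnpre",
                                               "vanilla_rnn", "gru"),
                                  T_values = c(20, 50, 100, 200),
                                  seeds = 1:5, d = 10, n = 3, tc = NULL,
                                  n_test = 1000) {
  if (is.null(tc)) tc <- train_config(stop_rule = "plateau")
  out <- list()
  for (Tv in T_values) for (f in families) for (s in seeds) {
    cfg <- family_config(f, d = d, n = n, N = 2)
    task <- task_spec("simple", N = 2, T = Tv, d = d)
    r <- train_eval(cfg, task, tc, seed = s, n_test = n_test)
    out[[length(out) + 1]] <- data.frame(family = f, T = Tv, seed = s,
                                         accuracy = r$acc, chance = 0.5,
                                         batches = r$fit$batches)
  }
  do.call(rbind, out)
}

#' Noise-robustness sweep
#'
#' Trains each family at a fixed signal-to-noise ratio
#' `alpha = E|x| / E|noise| = 10` (i.e. `noise_mag = 0.1` against
#' unit-magnitude codewords) and then evaluates, without retraining, on
#' noise levels spanning a grid of `alpha` values.
#'
#' @inheritParams sweep_capacity
#' @param alpha_values Signal-to-noise ratios to evaluate at.
#' @param alpha_train Training ratio (default 10).
#' @param N,d,n,T Geometry.
#' @return Data frame with `family`, `alpha`, `seed`, `accuracy`.
#' @export
sweep_noise <- function(families = c("mpn", "vanilla_rnn", "gru"),
                        alpha_values = c(0.3, 1, 2, 5, 10, 100),
                        alpha_train = 10, seeds = 1:5, N = 2, d = 50,
                        n = 100, T = 20, tc = NULL, n_test = 1000) {
  if (is.null(tc)) tc <- train_config()
  out <- list()
  for (f in families) for (s in seeds) {
    cfg <- family_config(f, d = d, n = n, N = N)
    task <- task_spec("simple", N = N, T = T, d = d,
                      noise_mag = 1 / alpha_train)
    fit <- train(cfg, task, tc, seed = s)
    for (a in alpha_values) {
      task_a <- task
      task_a$noise_mag <- 1 / a
      acc <- evaluate_accuracy(fit$params, task_a, fit$codebook, n_test,
                               seed = s + 7L)
      out[[length(out) + 1]] <- data.frame(family = f, alpha = a, seed = s,
                                           accuracy = acc, chance = 1 / N)
    }
  }
  do.call(rbind, out)
}

#' Long-time behavior: state magnitude and accuracy vs sequence/delay length
#'
#' Takes networks trained at a reference length (`T = 20` stimulus sweep;
#' `T_delay = 20` delay sweep) and, without retraining, feeds longer
#' stimulus sequences (or longer delays) while recording the normalized
#' final-state magnitude (`|M_(T-1)|_F / sqrt(nd)` for MPNs,
#' `|h_T|_2 / sqrt(n)` for RNNs) and accuracy.
#'
#' @param fits Named list of `"mpn_fit"` objects (e.g. MPNs at several
#'   `lambda_max` plus RNN baselines), all trained on compatible N = 2
#'   tasks.
#' @param lengths Stimulus lengths (or delay lengths when
#'   `sweep = "delay"`) to probe.
#' @param sweep `"stimulus"` or `"delay"`.
#' @param m Test sequences per point.
#' @param seed Optional seed.
#' @return Data frame with `name`, `length`, `magnitude`, `accuracy`.
#' @export
long_time_behavior <- function(fits, lengths = c(10, 20, 50, 100, 200),
                               sweep = c("stimulus", "delay"), m = 200,
                               seed = NULL) {
  sweep <- match.arg(sweep)
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- list()
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    cfg <- fit$config
    is_mpn <- cfg$family %in% c("mpn", "feedforward")
    for (L in lengths) {
      task <- fit$task
      if (sweep == "stimulus") {
        task$T <- as.integer(L + 1 + task$T_delay)
        task$T_stim <- as.integer(L)
      } else {
        task$T_delay <- as.integer(L)
        task$T <- as.integer(task$T_stim + L + 1)
      }
      b <- sample_batch(task, fit$codebook, m)
      if (is_mpn) {
        fw <- forward_pass(fit$params, b$X, m_times = task$T - 1L)
        mag <- mean(sqrt(colMeans(fw$M[, 1, ]^2)))
      } else {
        fw <- forward_pass(fit$params, b$X, ret_H = TRUE)
        mag <- mean(sqrt(colMeans(fw$H[, task$T, ]^2)))
      }
      acc <- mean(max.col(t(fw$Y)) == b$labels)
      out[[length(out) + 1]] <- data.frame(name = nm, length = L,
                                           magnitude = mag, accuracy = acc)
    }
  }
  do.call(rbind, out)
}

#' Activity-silent diagnostics on an integration-delay task
#'
#' For trained networks on the N-class integration-delay task, computes
#' per-time-step linear decoding accuracy of the label from hidden
#' activity, the mean hidden activity, the normalized time variability
#' (window `tau = 5`), and a cross-time decoding matrix over a subset of
#' times.
#'
#' @param fits Named list of fits (e.g. `list(mpn = ..., gru = ...)`) on
#'   the same task geometry.
#' @param m Test sequences.
#' @param decode_times Times at which to decode (default: all).
#' @param cross_times Times for the cross-time matrix (default: a coarse
#'   subset).
#' @param folds Cross-validation folds.
#' @param seed Optional seed.
#' @return A list per network with `decode` (data frame `t`, `accuracy`),
#'   `mean_activity`, `time_variability`, `cross_time` (matrix), and the
#'   chance level.
#' @export
activity_silent_report <- function(fits, m = 400, decode_times = NULL,
                                   cross_times = NULL, folds = 10,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- list()
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    Tn <- fit$task$T
    if (is.null(decode_times)) decode_times <- seq_len(Tn)
    if (is.null(cross_times)) {
      cross_times <- unique(round(seq(1, Tn, length.out = 6)))
    }
    st <- collect_states(fit, m = m, which = "hidden")
    labs <- st$ann$label[seq_len(m)]
    dec <- vapply(decode_times, function(t) {
      decoding_accuracy(st$X[st$ann$t == t, , drop = FALSE], labs,
                        folds = folds)
    }, 0)
    H <- forward_pass(fit$params, sample_batch(fit$task, fit$codebook,
                                               m)$X, ret_H = TRUE)$H
    out[[nm]] <- list(
      decode = data.frame(t = decode_times, accuracy = dec),
      mean_activity = mean_hidden_activity(H),
      time_variability = normalized_time_variability(H, tau = 5),
      cross_time = cross_time_decoding(st, labs, cross_times, cross_times,
                                       folds = folds),
      chance = 1 / fit$task$N)
  }
  out
}

#' Bounded-modulation comparison
#'
#' Trains MPNs with element-wise modulation bounds `m_b` in a grid
#' (including unbounded) on the two-class task and reports accuracy, the
#' learned `|eta|`, and the mean hidden-activity magnitude.
#'
#' @inheritParams sweep_capacity
#' @param m_b_values List of bounds; `NA` means unbounded.
#' @param N,d,n,T Geometry (paper-scale defaults).
#' @return Data frame with `m_b`, `seed`, `accuracy`, `abs_eta`,
#'   `mean_activity`.
#' @export
bounded_modulation_comparison <- function(m_b_values = c(NA, 1, 0.1),
                                          seeds = 1:5, N = 2, d = 50,
                                          n = 100, T = 20, tc = NULL,
                                          n_test = 1000) {
  if (is.null(tc)) tc <- train_config()
  out <- list()
  for (mb in m_b_values) for (s in seeds) {
    cfg <- model_config("mpn", d = d, n = n, N = N,
                        m_b = if (is.na(mb)) NULL else mb)
    task <- task_spec("simple", N = N, T = T, d = d)
    r <- train_eval(cfg, task, tc, seed = s, n_test = n_test)
    H <- forward_pass(r$fit$params,
                      sample_batch(task, r$fit$codebook, 200)$X,
                      ret_H = TRUE)$H
    out[[length(out) + 1]] <- data.frame(
      m_b = mb, seed = s, accuracy = r$acc,
      abs_eta = abs(r$fit$params$eta),
      mean_activity = mean(abs(H)))
  }
  do.call(rbind, out)
}

# ---- named presets ------------------------------------------------------

#' Run a named experiment preset
#'
#' Executes one of the package's preset experiment pipelines at desk scale
#' (reduced seed counts and grids; `full = TRUE` restores 10 seeds and the
#' full grids) and writes `metrics.json`, `tables/*.csv` and a
#' `manifest.json` recording seeds and configurations to `out_dir`.
#'
#' Presets: `fig3_dynamics` (trained-MPN/RNN state statistics: PR,
#' variance explained, readout alignment), `fig4_longtime`,
#' `fig5_delay` (activity-silent report), `fig6_capacity`, `fig6_noise`,
#' `fig6_echo`, `fig6_sequential`, `fig6_novel`, `fig7_context`,
#' `fig7_continuous`, `bounded_mods`, `postsyn_rule`.
#'
#' @param preset Preset name.
#' @param out_dir Output directory (created if missing).
#' @param seeds Integer seeds (default `1:5`; `full = TRUE` uses `1:10`).
#' @param tc Optional [train_config()] override applied to every training
#'   in the preset.
#' @param full Restore full-scale seed counts/grids?
#' @return (Invisibly) the list of result tables, which are also written
#'   to `out_dir`.
#' @export
reproduce <- function(preset, out_dir = tempfile("mpn_run_"), seeds = NULL,
                      tc = NULL, full = FALSE) {
  presets <- c("fig3_dynamics", "fig4_longtime", "fig5_delay",
               "fig6_capacity", "fig6_noise", "fig6_echo",
               "fig6_sequential", "fig6_novel", "fig7_context",
               "fig7_continuous", "bounded_mods", "postsyn_rule")
  if (!preset %in% presets) {
    stop("unknown preset; available: ", paste(presets, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(seeds)) seeds <- if (full) 1:10 else 1:5
  dir.create(file.path(out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  tables <- run_preset(preset, seeds, tc)
  for (nm in names(tables)) {
    if (is.data.frame(tables[[nm]])) {
      utils::write.csv(tables[[nm]],
                       file.path(out_dir, "tables", paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  metrics <- lapply(tables, function(x) {
    if (is.data.frame(x) && "accuracy" %in% names(x)) {
      mean(x$accuracy)
    } else if (is.numeric(x)) mean(x) else NULL
  })
  metrics <- metrics[!vapply(metrics, is.null, TRUE)]
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(preset = preset, seeds = seeds, full = full,
                            package_version =
                              as.character(utils::packageVersion("mpnet"))),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(tables)
}

run_preset <- function(preset, seeds, tc) {
  std <- function(...) if (is.null(tc)) train_config(...) else tc
  switch(preset,
    fig3_dynamics = {
      rows <- list()
      for (s in seeds) {
        for (f in c("mpn", "vanilla_rnn")) {
          cfg <- family_config(f, d = 50, n = 100, N = 2)
          task <- task_spec("simple", N = 2, T = 20, d = 50)
          fit <- train(cfg, task, std(), seed = s)
          st <- collect_states(fit, m = 1000, which = "hidden",
                               seed = s + 11L)
          rows[[length(rows) + 1]] <- data.frame(
            family = f, seed = s,
            accuracy = evaluate_accuracy(fit, n_examples = 1000,
                                         seed = s + 7L),
            pr = participation_ratio(fit_pca(st)),
            r2_input = variance_explained(st, "present_input"),
            r2_evidence = variance_explained(st, "accumulated_evidence"),
            alignment_nongo = mean(
              readout_alignment(fit, st)[c("evid1", "evid2", "null")]))
        }
      }
      list(dynamics = do.call(rbind, rows))
    },
    fig4_longtime = {
      fits <- list()
      for (lm in c(0.8, 0.95)) {
        cfg <- model_config("mpn", d = 50, n = 100, N = 2, lambda_max = lm)
        fits[[sprintf("mpn_lam%.2f", lm)]] <-
          train(cfg, task_spec("simple", N = 2, T = 20, d = 50), std(),
                seed = seeds[1])
      }
      fits$gru <- train(family_config("gru", d = 50, n = 100, N = 2),
                        task_spec("simple", N = 2, T = 20, d = 50), std(),
                        seed = seeds[1])
      list(longtime = long_time_behavior(fits, seed = seeds[1] + 3L))
    },
    fig5_delay = {
      task <- task_spec("simple", N = 3, T = 40, T_delay = 20, d = 50)
      fits <- list(
        mpn = train(family_config("mpn", d = 50, n = 100, N = 3), task,
                    std(), seed = seeds[1]),
        gru = train(family_config("gru", d = 50, n = 100, N = 3), task,
                    std(), seed = seeds[1]))
      rep5 <- activity_silent_report(fits, seed = seeds[1] + 3L)
      list(decode_mpn = rep5$mpn$decode, decode_gru = rep5$gru$decode)
    },
    fig6_capacity = list(capacity = sweep_capacity(seeds = seeds, tc = tc)),
    fig6_noise = list(noise = sweep_noise(seeds = seeds, tc = tc)),
    fig6_echo = {
      rows <- list()
      for (s in seeds) for (f in c("mpn", "vanilla_rnn", "gru")) {
        cfg <- family_config(f, d = 50, n = 100, N = 2)
        task <- task_spec("simple", N = 2, T = 20, d = 50)
        fit <- echo_state_protocol(cfg, task, tc, seed = s)
        rows[[length(rows) + 1]] <- data.frame(
          family = f, seed = s,
          accuracy = evaluate_accuracy(fit, n_examples = 1000,
                                       seed = s + 7L))
      }
      list(echo = do.call(rbind, rows))
    },
    fig6_sequential = {
      rows <- list()
      for (s in seeds) for (f in c("mpn", "gru")) {
        cfg <- family_config(f, d = 50, n = 100, N = 2)
        r <- sequential_learning_protocol(cfg, seed = s)
        rows[[length(rows) + 1]] <- data.frame(
          family = f, seed = s, acc_before = r$acc_A_before,
          acc_after = r$acc_A_after, excluded = r$excluded)
      }
      list(sequential = do.call(rbind, rows))
    },
    fig6_novel = {
      rows <- list()
      for (s in seeds) for (f in c("mpn", "gru")) {
        cfg <- family_config(f, d = 50, n = 100, N = 2)
        task <- task_spec("simple", N = 2, T = 20, d = 50)
        fit <- train(cfg, task, std(), seed = s)
        pr <- novel_class_probe(fit, m = 1000, seed = s + 11L)
        rows[[length(rows) + 1]] <- data.frame(
          family = f, seed = s,
          accuracy = decoding_accuracy(pr$states, pr$labels,
                                       seed = s + 13L))
      }
      list(novel = do.call(rbind, rows))
    },
    fig7_context = {
      rows <- list()
      for (s in seeds) {
        cfg <- family_config("mpn", d = 50, n = 100, N = 2)
        task <- task_spec("retro_context", T = 40, d = 50)
        fit <- train(cfg, task,
                     if (is.null(tc)) train_config(stop_rule = "plateau")
                     else tc, seed = s)
        rows[[length(rows) + 1]] <- data.frame(
          seed = s, accuracy = evaluate_accuracy(fit, n_examples = 1000,
                                                 seed = s + 7L))
      }
      list(context = do.call(rbind, rows))
    },
    fig7_continuous = {
      rows <- list()
      for (s in seeds) {
        cfg <- family_config("mpn", d = 50, n = 100, N = 2)
        task <- task_spec("continuous", T = 20, d = 50)
        fit <- train(cfg, task, std(), seed = s)
        rows[[length(rows) + 1]] <- data.frame(
          seed = s, accuracy = evaluate_accuracy(fit, n_examples = 1000,
                                                 seed = s + 7L))
      }
      list(continuous = do.call(rbind, rows))
    },
    bounded_mods = list(
      bounded = bounded_modulation_comparison(seeds = seeds, tc = tc)),
    postsyn_rule = {
      rows <- list()
      for (s in seeds) {
        cfg <- family_config("mpnpost", d = 50, n = 100, N = 2)
        task <- task_spec("simple", N = 2, T = 20, d = 50)
        r <- train_eval(cfg, task, std(), seed = s)
        rows[[length(rows) + 1]] <- data.frame(seed = s, accuracy = r$acc)
      }
      list(postsyn = do.call(rbind, rows))
    })
}
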