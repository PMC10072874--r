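test_that("initialization follows the Xavier scheme and is deterministic", {
  cfg <- model_config("mpn", d = 40, n = 3, N = 2)
  p <- init_params(cfg, 11)
  g <- sqrt(6 / 43)
  expect_true(all(abs(p$W_inp) <= g))
  expect_true(p$eta >= -3 && p$eta <= 3)
  expect_identical(p$lam, 0.95)
  expect_identical(p$b, numeric(3))
  expect_identical(p$b_RO, numeric(2))
  expect_identical(init_params(cfg, 11), p)  # bitwise
  expect_false(identical(init_params(cfg, 12)$W_inp, p$W_inp))
  # readout layer scaled by its own fans
  gro <- sqrt(6 / (2 + 3))
  expect_true(all(abs(p$W_RO) <= gro))
  expect_error(model_config("mpn", d = 0, n = 3, N = 2), "integers")
  expect_error(model_config("mpn", d = 5, n = 3, N = 2, lambda_max = 1.2),
               "lambda_max")
  expect_error(model_config("mpn", d = 5, n = 3, N = 2, m_b = -1), "m_b")
})

test_that("mpn_step matches hand-rolled scalar recursions and edge cases", {
  # scalar network: n = d = 1, W = 1, lam = 0.5, eta = 1
  cfg <- model_config("mpn", d = 1, n = 1, N = 1)
  p <- init_params(cfg, 1)
  p$W_inp <- matrix(1); p$eta <- 1; p$lam <- 0.5
  s1 <- mpn_step(p, matrix(0, 1, 1), 1)
  expect_equal(s1$h, tanh(1))
  expect_equal(s1$M[1, 1], tanh(1))
  s2 <- mpn_step(p, s1$M, 1)
  expect_equal(s2$h, tanh(1 + tanh(1)))
  expect_equal(s2$M[1, 1], 0.5 * tanh(1) + tanh(1 + tanh(1)))
  expect_equal(s2$h, 0.9427, tolerance = 1e-4)
  expect_equal(s2$M[1, 1], 1.3235, tolerance = 1e-4)

  # eta = 0 leaves the state at zero: pure feedforward layer
  cfg2 <- model_config("mpn", d = 6, n = 4, N = 2)
  p2 <- init_params(cfg2, 2); p2$eta <- 0
  x <- rnorm(6)
  s <- mpn_step(p2, matrix(0, 4, 6), x)
  expect_equal(s$h, drop(tanh(p2$W_inp %*% x)))
  expect_true(all(s$M == 0))

  # zero input: tanh(0) = 0 forces pure decay for every rule
  for (rule in c("associative", "presynaptic", "postsynaptic", "additive")) {
    cfgr <- model_config("mpn", rule = rule, d = 6, n = 4, N = 2)
    pr <- init_params(cfgr, 3)
    M0 <- matrix(rnorm(24), 4, 6)
    s <- mpn_step(pr, M0, numeric(6))
    expect_equal(s$h, numeric(4))
    expect_equal(s$M, pr$lam * M0)
  }
  expect_error(mpn_step(p2, matrix(0, 3, 6), x), "shape")
  expect_error(mpn_step(p2, matrix(NaN, 4, 6), x), "non-finite")
})

test_that("rnn_step and gru_step match hand computations", {
  cfg <- model_config("vanilla_rnn", d = 1, n = 1, N = 1)
  p <- init_params(cfg, 1)
  p$W_rec <- matrix(0.5); p$W_inp <- matrix(1); p$b <- 0
  h1 <- rnn_step(p, 0, 1)
  h2 <- rnn_step(p, h1, 1)
  expect_equal(h1, tanh(1))
  expect_equal(h2, tanh(0.5 * tanh(1) + 1))
  expect_equal(h2, 0.8813, tolerance = 5e-4)
  # W_rec = 0 reduces to the feedforward layer
  p$W_rec <- matrix(0)
  expect_equal(rnn_step(p, 0.7, 1), tanh(1))
  expect_equal(rnn_step(p, 0, 0), 0)

  cfgg <- model_config("gru", d = 1, n = 1, N = 1)
  pg <- init_params(cfgg, 1)
  for (nm in c("W_rec_u", "W_inp_u", "W_rec_r", "W_inp_r", "W_rec", "W_inp")) {
    pg[[nm]] <- matrix(1)
  }
  pg$b_u <- pg$b_r <- pg$b <- 0
  sig <- function(a) 1 / (1 + exp(-a))
  h1 <- gru_step(pg, 0, 1)
  expect_equal(h1, (1 - sig(1)) * tanh(1))
  expect_equal(h1, 0.20484, tolerance = 1e-4)
  # saturated update gate copies the previous state forward
  pg$b_u <- 100
  expect_equal(gru_step(pg, 0.37, 1), 0.37, tolerance = 1e-8)
  pg$b_u <- 0
  expect_equal(gru_step(pg, 0, 0), 0)
})

test_that("readout is affine with argmax classification", {
  cfg <- model_config("mpn", d = 4, n = 3, N = 3)
  p <- init_params(cfg, 4)
  expect_equal(readout(p, numeric(3)), numeric(3))
  # permutation readout permutes hidden components
  p$W_RO <- diag(3)[c(2, 3, 1), ]
  h <- c(0.3, -0.2, 0.9)
  expect_equal(readout(p, h), h[c(2, 3, 1)])
  # antisymmetric two-row readout decides by sign of r1 . h
  cfg2 <- model_config("mpn", d = 4, n = 3, N = 2)
  p2 <- init_params(cfg2, 5)
  r1 <- rnorm(3)
  p2$W_RO <- rbind(r1, -r1)
  for (i in 1:10) {
    h <- rnorm(3)
    expect_identical(unname(which.max(readout(p2, h))),
                     if (sum(r1 * h) > 0) 1L else 2L)
  }
})

test_that("run_sequence unrolls the step ops and is replayable", {
  for (fam in c("mpn", "vanilla_rnn", "gru")) {
    cfg <- model_config(fam, d = 6, n = 5, N = 2)
    p <- init_params(cfg, 6)
    set.seed(1)
    X <- rand_X(1, 6)
    tr <- run_sequence(p, X)
    if (fam == "mpn") {
      s <- mpn_step(p, matrix(0, 5, 6), X[1, ])
      expect_equal(tr$hidden[1, ], s$h)
      expect_equal(matrix(tr$states[2, ], 5, 6), s$M)
    } else {
      stepf <- if (fam == "vanilla_rnn") rnn_step else gru_step
      expect_equal(tr$hidden[1, ], stepf(p, numeric(5), X[1, ]))
    }
    X2 <- rand_X(7, 6)
    tr1 <- run_sequence(p, X2)
    tr2 <- run_sequence(p, tr1$inputs)
    expect_identical(tr1$states, tr2$states)  # bitwise replay
    expect_equal(tr1$outputs[7, ], as.numeric(tr1$y))
  }
  cfg <- model_config("mpn", d = 3, n = 2, N = 2)
  p <- init_params(cfg, 1)
  p$W_inp <- matrix(1e300, 2, 3); p$eta <- 1e300
  Xbad <- rbind(c(1, 1, 1), c(0, 1, 0), c(1, 0, 0))  # 0 * Inf makes NaN
  expect_error(run_sequence(p, Xbad, record = "hidden"), "non-finite")
})

test_that("go-signal projection maps states to post-go hidden activity", {
  cfg <- model_config("mpn", d = 8, n = 5, N = 2)
  p <- init_params(cfg, 7)
  x_go <- sqrt(2 / 8) * (runif(8) < 0.5)
  expect_equal(go_signal_projection(p, matrix(0, 5, 8), x_go),
               drop(tanh(p$W_inp %*% x_go)))
  # equals the network's own h_T on a noiseless go-terminated sequence
  set.seed(2)
  X <- rbind(rand_X(6, 8), x_go)
  tr <- run_sequence(p, X, record = c("hidden", "state"))
  M_Tm1 <- matrix(tr$states[7, ], 5, 8)  # state index T-1
  expect_equal(go_signal_projection(p, M_Tm1, x_go), tr$hidden[7, ],
               tolerance = 1e-12)
  # column-stacked projection of many states at once
  proj <- go_signal_projection(p, t(tr$states), x_go)
  expect_equal(dim(proj), c(5L, 8L))
  expect_equal(proj[, 7], go_signal_projection(p, M_Tm1, x_go))
})

test_that("unrolled modulation equals the recursion to machine precision", {
  set.seed(3)
  for (rule in c("associative", "presynaptic")) {
    for (rep in 1:3) {
      cfg <- model_config("mpn", rule = rule, d = 3, n = 4, N = 2)
      p <- init_params(cfg, rep)
      X <- rand_X(20, 3, scale = 1)
      tr <- run_sequence(p, X, record = "state")
      for (t in c(1, 7, 20)) {
        Mrec <- matrix(tr$states[t + 1, ], 4, 3)
        Mun <- unrolled_modulation(p, X, t)
        expect_lt(norm(Mun - Mrec, "F") / max(norm(Mrec, "F"), 1e-300),
                  1e-12)
      }
      # lam = 0 is memory-free: M_t depends on step t only
      p0 <- p; p0$lam <- 0
      tr0 <- run_sequence(p0, X, record = c("hidden", "state"))
      expected <- if (rule == "associative") {
        p0$eta * tcrossprod(tr0$hidden[5, ], X[5, ])
      } else {
        (p0$eta / 4) * matrix(X[5, ], 4, 3, byrow = TRUE)
      }
      expect_equal(matrix(tr0$states[6, ], 4, 3), expected)
    }
  }
  cfgb <- model_config("mpn", d = 3, n = 4, N = 2, m_b = 0.1)
  pb <- init_params(cfgb, 1)
  expect_error(unrolled_modulation(pb, rand_X(5, 3), 3), "bounds")
})

test_that("decay law, feedforward reduction, and bound enforcement hold", {
  set.seed(4)
  # decay law: zero inputs, M_{t+k} = lam^k M_t exactly
  for (rule in c("associative", "presynaptic", "postsynaptic", "additive")) {
    cfg <- model_config("mpn", rule = rule, d = 5, n = 4, N = 2)
    p <- init_params(cfg, 8)
    st <- mpn_step(p, matrix(rnorm(20), 4, 5), rnorm(5))
    M <- st$M
    for (k in 1:4) M <- mpn_step(p, M, numeric(5))$M
    expect_equal(M, p$lam^4 * st$M)
  }
  # eta = 0 makes the MPN bitwise equal to the feedforward network
  cfg <- model_config("mpn", d = 6, n = 5, N = 3)
  p <- init_params(cfg, 9); p$eta <- 0
  cfgf <- model_config("feedforward", d = 6, n = 5, N = 3)
  pf <- init_params(cfgf, 10)
  pf$W_inp <- p$W_inp; pf$W_RO <- p$W_RO
  X <- rand_X(9, 6)
  expect_identical(run_sequence(p, X, record = "hidden")$hidden,
                   run_sequence(pf, X, record = "hidden")$hidden)
  # bounds hold under adversarially large eta
  cfgb <- model_config("mpn", d = 5, n = 4, N = 2, m_b = 0.3)
  pb <- init_params(cfgb, 11); pb$eta <- 50
  M <- matrix(0, 4, 5)
  for (t in 1:15) {
    M <- mpn_step(pb, M, rnorm(5, sd = 2))$M
    expect_lte(max(abs(M)), 0.3)
  }
})

test_that("hidden-unit permutation leaves outputs unchanged", {
  set.seed(5)
  perm <- sample(6)
  X <- rand_X(7, 4)
  permute <- function(p, fam) {
    q <- p
    for (nm in intersect(names(p), c("W_inp", "W_inp_u", "W_inp_r"))) {
      q[[nm]] <- p[[nm]][perm, , drop = FALSE]
    }
    for (nm in intersect(names(p), c("W_rec", "W_rec_u", "W_rec_r"))) {
      q[[nm]] <- p[[nm]][perm, perm, drop = FALSE]
    }
    for (nm in intersect(names(p), c("b", "b_u", "b_r"))) {
      q[[nm]] <- p[[nm]][perm]
    }
    q$W_RO <- p$W_RO[, perm, drop = FALSE]
    q
  }
  for (fam in c("mpn", "vanilla_rnn", "gru")) {
    cfg <- model_config(fam, d = 4, n = 6, N = 3)
    p <- init_params(cfg, 12)
    if (fam == "gru") { p$b_u <- rnorm(6); p$b_r <- rnorm(6) }
    q <- permute(p, fam)
    expect_equal(run_sequence(q, X)$y, run_sequence(p, X)$y,
                 tolerance = 1e-12)
  }
})

test_that("parameter-count formulas match exact trainable-entry enumeration", {
  expect_equal(count_trainable_params(
    model_config("mpn", d = 40, n = 3, N = 2))$core, 125)
  expect_equal(count_trainable_params(
    model_config("gru", d = 10, n = 3, N = 2))$core, 126)
  expect_equal(count_trainable_params(
    model_config("feedforward", d = 1, n = 1, N = 1))$core, 2)
  expect_equal(count_trainable_params(
    list(family = "lstm", n = 3, d = 10, N = 2, readout_bias = FALSE))$core,
    4 * 3 * (3 + 10 + 1))
  set.seed(6)
  for (i in 1:20) {
    n <- sample(1:12, 1); d <- sample(1:12, 1); N <- sample(1:5, 1)
    fam <- sample(c("feedforward", "mpn", "vanilla_rnn", "gru"), 1)
    hb <- sample(c(TRUE, FALSE), 1); rb <- sample(c(TRUE, FALSE), 1)
    cfg <- model_config(fam, d = d, n = n, N = N, hidden_bias = hb,
                        readout_bias = rb)
    p <- init_params(cfg, i)
    live <- sum(vapply(mpnet:::trainable_names(cfg),
                       function(nm) length(p[[nm]]), integer(1)))
    cts <- count_trainable_params(cfg)
    expect_equal(cts$live_core + cts$live_readout, live)
    # formula counts a bias per layer by convention
    full_bias <- switch(fam, feedforward = , mpn = n,
                        vanilla_rnn = n, gru = 3 * n)
    hb_n <- if (hb) n else 0
    gru_gate_b <- if (fam == "gru") 2 * n else 0
    expect_equal(cts$core - (full_bias - hb_n - gru_gate_b),
                 cts$live_core)
  }
})
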