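test_that("participation ratio matches a brute-force spectrum computation", {
  expect_equal(participation_ratio(c(1, 0, 0)), 1)
  expect_equal(participation_ratio(rep(1 / 7, 7)), 7)
  expect_equal(participation_ratio(rep(0.2, 5) * 3), 5)  # scale invariant
  set.seed(31)
  for (i in 1:10) {
    # random covariance; PR from eigenvalues computed independently
    A <- matrix(rnorm(36), 6, 6)
    S <- crossprod(A)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(participation_ratio(ev / sum(ev)),
                 sum(ev)^2 / sum(ev^2), tolerance = 1e-10)
  }
  expect_error(participation_ratio(c(-1, 2)), "nonnegative")
  expect_error(participation_ratio(c(0, 0)), "zero")
})

test_that("fit_pca is centered, orthonormal, sign-fixed, row-order invariant", {
  set.seed(32)
  X <- matrix(rnorm(600), 100, 6) %*% diag(c(3, 2, 1, 0.5, 0.2, 0.1))
  pc <- fit_pca(X)
  expect_equal(sum(pc$var_ratio), 1)
  expect_equal(unname(crossprod(pc$rotation)), diag(6), tolerance = 1e-10)
  # sign fix: largest loading positive
  for (j in 1:6) {
    expect_gt(pc$rotation[which.max(abs(pc$rotation[, j])), j], 0)
  }
  # reconstruction with all components reproduces the centered data
  ctr <- sweep(X, 2, pc$center)
  expect_equal(ctr %*% pc$rotation %*% t(pc$rotation), ctr,
               tolerance = 1e-8)
  # row order does not matter
  pc2 <- fit_pca(X[sample(nrow(X)), ])
  expect_equal(unname(abs(colSums(pc$rotation * pc2$rotation))), rep(1, 6),
               tolerance = 1e-8)
  # rank-1 data concentrates all variance in one component
  X1 <- outer(rnorm(50), c(1, 2, 3))
  expect_equal(fit_pca(X1)$var_ratio[1], 1, tolerance = 1e-10)
  # isotropic data spreads variance roughly evenly
  Xi <- matrix(rnorm(3000 * 3), 3000, 3)
  expect_equal(fit_pca(Xi)$var_ratio, rep(1 / 3, 3), tolerance = 0.1)
  # zero-variance input is flagged degenerate
  expect_true(fit_pca(matrix(1, 10, 3))$degenerate)
})

test_that("variance explained is exact for linear states, ~0 for noise", {
  set.seed(33)
  n_obs <- 600
  ann <- data.frame(example = seq_len(n_obs), t = 1,
                    label = sample(1:2, n_obs, TRUE),
                    symbol = sample(c("null", "evid1", "evid2", "go"),
                                    n_obs, TRUE),
                    rel_evidence = sample(-5:5, n_obs, TRUE))
  # states an exact linear function of the evidence
  X <- outer(ann$rel_evidence, c(0.5, -1, 2))
  expect_equal(variance_explained(X, "accumulated_evidence", ann), 1)
  # independent states
  Xn <- matrix(rnorm(n_obs * 3), n_obs, 3)
  expect_lt(variance_explained(Xn, "accumulated_evidence", ann), 0.02)
  expect_lt(variance_explained(Xn, "present_input", ann), 0.02)
  # exact function of the symbol identity
  mu <- c(null = 0, evid1 = 1, evid2 = -1, go = 3)
  Xs <- outer(mu[ann$symbol], c(1, 2, -1))
  expect_equal(variance_explained(Xs, "present_input", ann), 1)
  # 1-D states, scalar predictor: equals squared correlation (both methods)
  x1 <- matrix(0.3 * ann$rel_evidence + rnorm(n_obs), ncol = 1)
  r2 <- cor(x1[, 1], ann$rel_evidence)^2
  expect_equal(variance_explained(x1, "accumulated_evidence", ann), r2)
  expect_equal(variance_explained(x1, "accumulated_evidence", ann,
                                  method = "pooled"), r2)
  # bounded in [0, 1]
  v <- variance_explained(Xn, "present_input", ann)
  expect_true(v >= 0 && v <= 1)
  ann$rel_evidence <- 1
  expect_error(variance_explained(X, "accumulated_evidence", ann),
               "constant")
})

test_that("linear decoding is perfect on separated clusters, chance on noise", {
  set.seed(34)
  n_per <- 60
  X2 <- rbind(matrix(rnorm(n_per * 4), n_per, 4),
              matrix(rnorm(n_per * 4, mean = 5), n_per, 4))
  y2 <- rep(1:2, each = n_per)
  expect_gte(decoding_accuracy(X2, y2, folds = 10, seed = 1), 0.95)
  # three separated clusters exercise the one-vs-rest path
  X3 <- rbind(matrix(rnorm(n_per * 4, 0), n_per, 4),
              matrix(rnorm(n_per * 4, 6), n_per, 4),
              cbind(matrix(rnorm(n_per * 2, -6), n_per, 2),
                    matrix(rnorm(n_per * 2, 6), n_per, 2)))
  y3 <- rep(1:3, each = n_per)
  expect_gte(decoding_accuracy(X3, y3, folds = 10, seed = 2), 0.95)
  # shuffled labels decode at chance (1/N within 3 binomial sigmas)
  ysh <- sample(y2)
  acc <- decoding_accuracy(X2, ysh, folds = 10, seed = 3)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / length(ysh)) + 0.05)
  expect_error(decoding_accuracy(X2, rep(1, nrow(X2))), "two classes")
  expect_error(decoding_accuracy(X2[1:12, ], y2[c(1:6, 61:66)], folds = 10),
               "folds")
})

test_that("cross-time decoding has a same-time diagonal and flat constants", {
  set.seed(35)
  # synthetic mpn_states: separable at every t, same geometry across time
  m <- 80; times <- 1:3; n <- 4
  labels <- rep(1:2, each = m / 2)
  mk_states <- function(drift) {
    X <- do.call(rbind, lapply(times, function(t) {
      matrix(rnorm(m * n), m, n) + outer(ifelse(labels == 1, 3, -3) +
                                           drift * t, rep(1, n))
    }))
    structure(list(X = X,
                   ann = data.frame(example = rep(seq_len(m), length(times)),
                                    t = rep(times, each = m),
                                    label = rep(labels, length(times)),
                                    symbol = "x", rel_evidence = 0),
                   which = "hidden", m = m, times = times, n = n, d = 1,
                   family = "mpn"), class = "mpn_states")
  }
  st <- mk_states(0)
  cm <- cross_time_decoding(st, labels, folds = 5, seed = 4)
  expect_identical(dim(cm), c(3L, 3L))
  expect_true(all(cm > 0.9))  # time-constant geometry: matrix ~constant
  # diagonal equals same-time decoding within fold noise
  d1 <- decoding_accuracy(st$X[st$ann$t == 1, ], labels, folds = 5, seed = 4)
  expect_lt(abs(cm[1, 1] - d1), 0.1)
})

test_that("readout alignment is 1 along a readout and 0 orthogonal to it", {
  cfg <- model_config("mpn", d = 4, n = 6, N = 2)
  p <- init_params(cfg, 36)
  r1 <- c(1, 0, 0, 0, 0, 0)
  p$W_RO <- rbind(r1, r1)
  set.seed(37)
  # cluster varying only along the readout direction
  X_along <- outer(rnorm(200), r1)
  # cluster varying orthogonally
  X_orth <- cbind(0, matrix(rnorm(200 * 5), 200, 5))
  st <- structure(list(
    X = rbind(X_along, X_orth),
    ann = data.frame(example = 1, t = 1, label = 1,
                     symbol = rep(c("a", "b"), each = 200),
                     rel_evidence = 0),
    which = "hidden"), class = "mpn_states")
  al <- readout_alignment(p, st)
  expect_equal(unname(al["a"]), 1, tolerance = 1e-6)
  expect_lt(unname(al["b"]), 0.05)
})

test_that("state magnitudes and time variability have closed-form cases", {
  expect_equal(normalized_state_magnitude(matrix(0, 3, 4)), 0)
  expect_equal(normalized_state_magnitude(matrix(-2, 3, 4)), 2)
  expect_equal(normalized_state_magnitude(rep(0.7, 10), "rnn"), 0.7)
  # constant activity: zero variability
  H <- array(1, c(3, 8, 2))
  v <- normalized_time_variability(H, tau = 4)
  expect_true(all(is.na(v[1:3])))
  expect_equal(v[4:8], rep(0, 5))
  # alternating +-c over an even window: variance = mean square = c^2
  h <- matrix(rep(c(0.5, -0.5), 6), 1, 12)
  v2 <- normalized_time_variability(h, tau = 4)
  expect_equal(v2[4:12], rep(1, 9))
  # zero-energy windows are excluded rather than propagating NaN
  h3 <- rbind(matrix(0, 1, 12), h)
  v3 <- normalized_time_variability(h3, tau = 4)
  expect_equal(v3[4:12], rep(1, 9))
})

test_that("readout difference matches a brute-force grouping oracle", {
  task <- task_spec("retro_context", T = 16, d = 10, ctx_pre_delay = 2,
                    ctx_post_delay = 2, T_context = 2)
  cfg <- model_config("mpn", d = 10, n = 8, N = 2)
  fit <- train(cfg, task, micro_tc(max_batches = 30), seed = 38)
  dy <- readout_difference(fit, m = 200, seed = 39)
  expect_identical(dim(dy), c(17L, 2L, 2L))
  expect_true(all(is.finite(dy)))
  # brute-force recomputation from raw projected outputs
  set.seed(39)
  b <- sample_batch(fit$task, fit$codebook, 200)
  fw <- mpnet:::forward_pass(fit$params, b$X,
                             x_go = fit$codebook$vectors[, "go"])
  yg <- apply(fw$Hgo, c(2, 3), function(h) fit$params$W_RO %*% h)
  # yg: N x (T+1) x B
  for (tau in 1:2) for (cc in 1:2) {
    idx1 <- b$labels_sub[, tau] == 1 & b$context == cc
    idx2 <- b$labels_sub[, tau] == 2 & b$context == cc
    y1 <- apply(yg[, , idx1, drop = FALSE], c(1, 2), mean)
    y2 <- apply(yg[, , idx2, drop = FALSE], c(1, 2), mean)
    expect_equal(as.numeric(dy[, tau, cc]),
                 unname(0.5 * (y1[1, ] - y1[2, ]) + 0.5 * (y2[2, ] - y2[1, ])),
                 tolerance = 1e-10)
  }
  # antisymmetry: swapping which label fills each slot flips the sign
  for (tau in 1:2) for (cc in 1:2) {
    idx1 <- b$labels_sub[, tau] == 1 & b$context == cc
    idx2 <- b$labels_sub[, tau] == 2 & b$context == cc
    y1 <- apply(yg[, , idx2, drop = FALSE], c(1, 2), mean)  # swapped in
    y2 <- apply(yg[, , idx1, drop = FALSE], c(1, 2), mean)
    swapped <- 0.5 * (y1[1, ] - y1[2, ]) + 0.5 * (y2[2, ] - y2[1, ])
    expect_equal(unname(swapped), -as.numeric(dy[, tau, cc]),
                 tolerance = 1e-10)
  }
})

test_that("attractor angle shift recovers planted rotations", {
  set.seed(40)
  base <- matrix(rnorm(500 * 4), 500, 4)
  X1 <- cbind(base[, 1] * 5, base[, 2], base[, 3], base[, 4]) / 2
  p1 <- fit_pca(X1)
  expect_equal(attractor_angle_shift(p1, p1), 0, tolerance = 1e-8)
  # orthogonal top components
  X2 <- cbind(base[, 1], base[, 2] * 5, base[, 3], base[, 4]) / 2
  p2 <- fit_pca(X2)
  expect_equal(attractor_angle_shift(p1, p2), 90, tolerance = 1)
  # planted 30-degree rotation of the dominant direction
  th <- 30 * pi / 180
  R <- diag(4); R[1, 1] <- cos(th); R[2, 2] <- cos(th)
  R[1, 2] <- -sin(th); R[2, 1] <- sin(th)
  p3 <- fit_pca(X1 %*% t(R))
  expect_equal(attractor_angle_shift(p1, p3), 30, tolerance = 2)
})
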