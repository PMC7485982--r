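test_that("dictionary geometry matches the standard configurations", {
  d1 <- build_dictionary(100, 0.25, 0.05, 0.018)
  expect_equal(dim(d1$G), c(25L, 5L))
  expect_equal(d1$atom_centers, seq(0, 0.2, by = 0.05))
  expect_true(all(d1$G > 0))
  d2 <- build_dictionary(100, 0.30, 0.02, 8.5e-3)
  expect_equal(dim(d2$G), c(30L, 15L))
  expect_equal(range(d2$atom_centers), c(0, 0.28))
  # single atom at lag 0 with a tiny width is close to a unit column
  d3 <- build_dictionary(100, 0.10, 0.10, 1e-6)
  expect_equal(ncol(d3$G), 1L)
  expect_equal(d3$G[1, 1], 1)
  expect_lt(max(d3$G[-1, 1]), 1e-6)
  expect_error(build_dictionary(100, 0.25, 0.3, 0.018), "no atoms")
})

test_that("lag embedding has delay-line semantics", {
  L <- 5; t0 <- 4
  # constant envelope: every lag vector is constant after burn-in
  des_c <- build_design(cbind(rep(2, 20), rep(0, 20)), 100, L, t0)
  expect_true(all(des_c$S[[3]][1:L, ] == 2))
  # unit impulse at sample k appears at lag t - k
  e <- rep(0, 20); e[7] <- 1
  des_i <- build_design(cbind(e, rep(0, 20)), 100, L, t0)
  S_full <- do.call(cbind, des_i$S)
  for (t in 1:20) for (l in 1:L)
    expect_equal(S_full[l, t], as.numeric(t - (l - 1) == 7))
})

test_that("windowed reconstruction equals the direct convolution sum", {
  set.seed(71)
  L <- 6; t0 <- 3; Tn <- 30
  env <- cbind(rnorm(Tn), rnorm(Tn))
  dict <- build_dictionary(100, L / 100, 2 / 100, 4e-4)
  des <- build_design(env, 100, L, t0)
  x <- rnorm(2 * dict$D)
  tau <- as.numeric(dict$Gtilde %*% x)   # (tau1; tau2), length 2L
  recon <- unlist(lapply(des$S, function(S) as.numeric(crossprod(S, tau))))
  direct <- vapply(seq_len(Tn), function(t) {
    acc <- 0
    for (l in 1:L) {
      if (t - l + 1 >= 1) {
        acc <- acc + env[t - l + 1, 1] * tau[l] + env[t - l + 1, 2] * tau[L + l]
      }
    }
    acc
  }, numeric(1))
  expect_equal(recon, direct, tolerance = 1e-10)
})

test_that("RLS reduces to per-window least squares and shrinks under heavy penalty", {
  set.seed(72)
  Tn <- 60; t0 <- 10
  env <- cbind(rnorm(Tn), rnorm(Tn))
  dict <- build_dictionary(100, 0.05, 0.01, 1e-4)
  des <- build_design(env, 100, dict$L, t0)
  y <- rnorm(Tn)
  p <- 2 * dict$D
  # lambda = 0, small ridge: per-window regularized least squares
  fit0 <- rls_fit(des, y, dict, 0, 1e-8)
  maps <- dyntrf:::design_obs_maps(des, dict)
  for (n in 1:des$N) {
    B <- maps[[n]]
    direct <- solve(crossprod(B) + diag(1e-8, p),
                    crossprod(B, y[(n - 1) * t0 + 1:t0]))
    expect_equal(fit0$states[, n], as.numeric(direct), tolerance = 1e-6)
  }
  # gamma enormous: estimates collapse to zero
  fit_big <- rls_fit(des, y, dict, 0.5, 1e9)
  expect_lt(max(abs(fit_big$states)), 1e-6)
  # direct weighted normal-equation oracle for lambda in (0, 1)
  lam <- 0.8
  fit_l <- rls_fit(des, y, dict, lam, 0.1)
  n <- des$N
  Phi <- diag(0.1, p); beta <- rep(0, p)
  for (i in 1:n) {
    w <- lam^(n - i)
    B <- maps[[i]]
    Phi <- Phi + w * crossprod(B)
    beta <- beta + w * as.numeric(crossprod(B, y[(i - 1) * t0 + 1:t0]))
  }
  expect_equal(fit_l$states[, n],
               as.numeric(solve(Phi - diag(0.1, p) + diag(0.1, p), beta)),
               tolerance = 1e-8)
  expect_error(rls_fit(des, y, dict, 1, 0.1), "lambda")
})

test_that("l1-penalized RLS matches the soft-threshold solution elementwise", {
  set.seed(73)
  Tn <- 40; t0 <- 10
  env <- cbind(rnorm(Tn), rnorm(Tn))
  dict <- build_dictionary(100, 0.03, 0.01, 1e-4)
  des <- build_design(env, 100, dict$L, t0)
  y <- rnorm(Tn)
  fit <- rls_fit(des, y, dict, 0, 0.5, penalty = "l1")
  maps <- dyntrf:::design_obs_maps(des, dict)
  # KKT check: |gradient| <= gamma at zeros, = gamma with matching sign else
  for (n in 1:des$N) {
    B <- maps[[n]]
    g <- as.numeric(crossprod(B) %*% fit$states[, n]) -
      as.numeric(crossprod(B, y[(n - 1) * t0 + 1:t0]))
    at_zero <- abs(fit$states[, n]) < 1e-10
    expect_true(all(abs(g[at_zero]) <= 0.5 + 1e-6))
    if (any(!at_zero))
      expect_equal(g[!at_zero], -0.5 * sign(fit$states[!at_zero, n]),
                   tolerance = 1e-5)
  }
})

test_that("forgetting factor near one approaches the all-data least squares", {
  set.seed(74)
  Tn <- 200; t0 <- 10
  env <- cbind(rnorm(Tn), rnorm(Tn))
  dict <- build_dictionary(100, 0.03, 0.01, 1e-4)
  des <- build_design(env, 100, dict$L, t0)
  x_true <- rnorm(2 * dict$D)
  maps <- dyntrf:::design_obs_maps(des, dict)
  y <- unlist(lapply(seq_len(des$N), function(n)
    as.numeric(maps[[n]] %*% x_true))) + rnorm(Tn, 0, 0.1)
  fit <- rls_fit(des, y, dict, 1 - 1e-9, 1e-8)
  p <- 2 * dict$D
  Phi <- Reduce(`+`, lapply(maps, crossprod))
  beta <- Reduce(`+`, lapply(seq_len(des$N), function(n)
    as.numeric(crossprod(maps[[n]], y[(n - 1) * t0 + 1:t0]))))
  ls <- solve(Phi + diag(1e-8, p), beta)
  expect_equal(fit$states[, des$N], as.numeric(ls), tolerance = 1e-4)
})

test_that("cross-validated penalty selection is reproducible and sane", {
  set.seed(75)
  Tn <- 120; t0 <- 10
  env <- cbind(rnorm(Tn), rnorm(Tn))
  dict <- build_dictionary(100, 0.03, 0.01, 1e-4)
  des <- build_design(env, 100, dict$L, t0)
  maps <- dyntrf:::design_obs_maps(des, dict)
  x_true <- rnorm(2 * dict$D)
  y <- unlist(lapply(seq_len(des$N), function(n)
    as.numeric(maps[[n]] %*% x_true))) + rnorm(Tn, 0, 0.05)
  # singleton candidate set returns the candidate
  expect_equal(choose_gamma(des, y, dict, 0.9, gammas = 3.3)$gamma, 3.3)
  # near-noiseless well-conditioned data prefer the smallest penalty
  sel <- choose_gamma(des, y, dict, 0.9, gammas = c(0.01, 1, 100))
  expect_equal(sel$gamma, 0.01)
  # reported scores equal a direct recomputation for one candidate
  g <- 1
  half <- des$N %/% 2
  mse <- 0
  for (k in 1:2) {
    train <- if (k == 1) 1:half else (half + 1):des$N
    test <- setdiff(1:des$N, train)
    d2 <- des; d2$S <- des$S[train]; d2$N <- length(train)
    d2$T_used <- length(train) * t0
    ytr <- unlist(lapply(train, function(n) y[(n - 1) * t0 + 1:t0]))
    f <- rls_fit(d2, ytr, dict, 0.9, g)
    xh <- f$states[, ncol(f$states)]
    for (n in test)
      mse <- mse + mean((y[(n - 1) * t0 + 1:t0] - as.numeric(maps[[n]] %*% xh))^2)
  }
  expect_equal(as.numeric(sel$cv_mse["1"]), mse / des$N, tolerance = 1e-10)
})

test_that("single-regime MSAR reduces to the AR(1) innovation fit", {
  set.seed(76)
  x <- matrix(cumsum(rnorm(100, 0, 0.3)), 1)
  m <- msar_fit(x, 1, list(max_iters = 100))
  # fixed point of the coordinate updates: alpha given mu, mu given alpha
  a <- m$alpha[1]; mu <- m$mu[1, 1]
  N <- 100
  xp <- x[1, -N]; xn <- x[1, -1]
  expect_equal(a, sum(xp * (xn - mu)) / sum(xp^2), tolerance = 1e-6)
  expect_equal(mu, mean(xn - a * xp), tolerance = 1e-6)
  v <- xn - a * xp - mu
  expect_equal(m$Q[[1]][1, 1], mean(v^2), tolerance = 1e-5)
  expect_gt(min(diff(m$logliks)), -1e-8)
})

test_that("MSAR recovers well-separated regimes and stays row-stochastic", {
  accs <- vapply(1:20, function(s) {
    set.seed(1300 + s)
    N <- 200
    st <- numeric(N); st[1] <- 1
    P <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
    for (n in 2:N) st[n] <- sample(1:2, 1, prob = P[st[n - 1], ])
    x <- numeric(N)
    # strongly contrasting regimes: near-white AR(0.05) with unit noise vs
    # a smooth AR(0.95) with small noise
    for (n in 2:N) x[n] <- c(0.05, 0.95)[st[n]] * x[n - 1] +
      rnorm(1, 0, c(1, 0.1)[st[n]])
    m <- msar_fit(matrix(x, 1), 2, list(seed = s, max_iters = 60))
    expect_equal(rowSums(m$P), c(1, 1), tolerance = 1e-8)
    dec <- apply(m$gamma, 2, which.max)
    truth <- st[-1]
    max(mean(dec == truth), mean(3 - dec == truth))
  }, numeric(1))
  expect_gte(median(accs), 0.9)
})

test_that("MSAR one-step estimates follow the regime-averaged formula", {
  dict <- build_dictionary(100, 0.02, 0.01, 1e-4)
  D2 <- 2 * dict$D
  X <- matrix(rnorm(D2 * 6), D2, 6)
  model <- structure(list(J = 2, pi0 = c(0.5, 0.5),
                          P = matrix(0.5, 2, 2),
                          alpha = c(0.3, 0.8),
                          mu = matrix(c(0.1, -0.1, 0.2, 0), D2, 2),
                          Q = list(diag(D2), diag(D2)),
                          omega = matrix(c(0.7, 0.3), 2, 5)),
                     class = "msar_model")
  est <- msar_estimate(model, X, dict, 3)
  for (n in 2:6) {
    pred <- 0.7 * (model$mu[, 1] + 0.3 * X[, n - 1]) +
      0.3 * (model$mu[, 2] + 0.8 * X[, n - 1])
    expect_equal(est$states[, n], pred, tolerance = 1e-12)
  }
  # one-hot regime weights give the single-regime prediction
  model$omega <- matrix(c(1, 0), 2, 5)
  est1 <- msar_estimate(model, X, dict, 3)
  expect_equal(est1$states[, 3], model$mu[, 1] + 0.3 * X[, 2], tolerance = 1e-12)
})

test_that("M100 extraction and attention decoding follow their definitions", {
  dict <- build_dictionary(100, 0.25, 0.05, 0.018^2)
  N <- 10
  tau1 <- matrix(0.1, dict$L, N)
  tau2 <- matrix(0.1, dict$L, N)
  lag150 <- which.min(abs(dict$lags - 0.15))
  tau1[lag150, ] <- -2                       # dip of -2 at 150 ms
  trf <- structure(list(tau1 = tau1, tau2 = tau2, lags = dict$lags,
                        time_s = seq_len(N), t0 = 30, F_s = 100,
                        estimator = "test"), class = "trf_series")
  m <- extract_m100(trf)
  expect_equal(m$m100_1, rep(2, N))
  # all-positive kernel: magnitude of the smallest positive value, flagged
  expect_equal(m$m100_2, rep(0.1, N))
  expect_true(all(m$degenerate[, 2]))
  expect_false(any(m$degenerate[, 1]))
  expect_error(extract_m100(trf, c(0.5, 0.6)), "outside")

  dec <- decode_attention(m$difference, rep(1, N))
  expect_equal(dec$misclassification_rate, 0)
  dec2 <- decode_attention(m$difference, rep(2, N))
  expect_equal(dec2$misclassification_rate, 100)
  diffs <- c(1, 1, -1, 1, -1, 1, 1, -1, 1, 1)
  sched <- rep(1, 10)
  expect_equal(decode_attention(diffs, sched)$misclassification_rate, 30)
  expect_error(decode_attention(diffs, rep(1, 3)), "lengths differ")
  # exact zero difference counts as misclassified
  expect_equal(decode_attention(c(0, 1), c(2, 1))$misclassification_rate, 50)
})

test_that("GM backend with one component equals the Gaussian backend", {
  set.seed(77)
  sc <- scenario_spec(duration_s = 12, snr_db = 5, seed = 3)
  tr <- simulate_scenario(sc)
  cfg <- em_config(max_iters = 10, diagonal_only = TRUE, seed = 1)
  g <- fit_trf_ssm(tr$design, tr$y, tr$dict, backend = "gaussian",
                   alpha = sc$alpha, config = cfg)
  m <- fit_trf_ssm(tr$design, tr$y, tr$dict, backend = "gm", M = 1,
                   W = sc$W, alpha = sc$alpha, config = cfg)
  expect_equal(m$trf$tau1, g$trf$tau1, tolerance = 1e-8)
  expect_equal(m$trf$tau2, g$trf$tau2, tolerance = 1e-8)
})

test_that("dictionary scale is absorbed by the states", {
  set.seed(78)
  Tn <- 60; t0 <- 10
  env <- cbind(rnorm(Tn), rnorm(Tn))
  dict <- build_dictionary(100, 0.05, 0.01, 1e-4)
  des <- build_design(env, 100, dict$L, t0)
  y <- rnorm(Tn)
  dict2 <- dict
  dict2$G <- 2 * dict$G
  dict2$Gtilde <- 2 * dict$Gtilde
  # the ridge must co-scale (gamma ~ scale^2) for exact equivalence
  f1 <- rls_fit(des, y, dict, 0, 1e-8)
  f2 <- rls_fit(des, y, dict2, 0, 4e-8)
  expect_equal(f2$states, f1$states / 2, tolerance = 1e-6)
  expect_equal(f2$tau1, f1$tau1, tolerance = 1e-6)
  expect_equal(f2$tau2, f1$tau2, tolerance = 1e-6)
})
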