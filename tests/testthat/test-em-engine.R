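test_that("M-step reduces to the textbook Gaussian update for one component", {
  set.seed(61)
  K <- 6; d <- 2
  mom <- dyntrf:::empty_moments(K, 1L, d)
  e1s <- matrix(rnorm(K * d), K, d)
  for (i in 1:K) {
    mom$e0[i, 1] <- 1
    mom$e1[i, 1, ] <- e1s[i, ]
    mom$e2[[i]] <- crossprod(matrix(rnorm(4), 2)) + diag(2) +
      tcrossprod(e1s[i, ])
    mom$xx_prev[[i]] <- diag(2); mom$x_xprev[[i]] <- diag(2)
  }
  model0 <- gm_noise_model(1, matrix(0, d, 1), list(diag(2)), W = 1)
  up <- m_step_update(mom, model0)
  mu_hat <- colMeans(e1s)
  expect_equal(up$means[, 1], mu_hat, tolerance = 1e-12)
  E2 <- Reduce(`+`, mom$e2[1:K]) / K
  expect_equal(up$covs[[1]], E2 - tcrossprod(mu_hat), tolerance = 1e-12)
  expect_equal(sum(up$probs), 1)
})

test_that("M-step matches a direct weighted-moment calculation", {
  # hand-built two-window, two-component scalar moments
  mom <- dyntrf:::empty_moments(2L, 2L, 1L)
  e0 <- matrix(c(0.8, 0.3, 0.2, 0.7), 2, 2)
  e1 <- array(0, c(2, 2, 1)); e1[, , 1] <- matrix(c(0.5, -0.2, 0.1, 0.9), 2, 2)
  e2v <- matrix(c(0.6, 0.3, 0.2, 1.4), 2, 2)
  mom$e0 <- e0; mom$e1 <- e1
  for (i in 1:2) for (m in 1:2) {
    k <- dyntrf:::mom_idx(mom, i, m)
    mom$e2[[k]] <- matrix(e2v[i, m], 1, 1)
    mom$xx_prev[[k]] <- matrix(1, 1, 1); mom$x_xprev[[k]] <- matrix(1, 1, 1)
  }
  model0 <- gm_noise_model(c(0.5, 0.5), matrix(0, 1, 2),
                           list(matrix(1, 1, 1), matrix(1, 1, 1)), W = 1)
  up <- m_step_update(mom, model0)
  for (m in 1:2) {
    denom <- sum(e0[, m])
    mu <- sum(e1[, m, 1]) / denom
    expect_equal(up$probs[m], denom / 2, tolerance = 1e-12)
    expect_equal(up$means[1, m], mu, tolerance = 1e-12)
    expect_equal(up$covs[[m]][1, 1],
                 max(sum(e2v[, m]) / denom - mu^2, 1e-10), tolerance = 1e-12)
  }
})

test_that("observation-noise update recovers a known variance", {
  errs <- vapply(1:20, function(s) {
    set.seed(700 + s)
    spec <- random_scalar_spec(400, sigma2 = 1)
    model <- gm_noise_model(1, matrix(0, 1, 1), list(matrix(0.3, 1, 1)), W = 1)
    sim <- simulate_gm_ssm(spec, model)
    sm <- two_filter_gm_smoother(spec, model, sim$y)
    update_sigma2(spec, sm, sim$y)
  }, numeric(1))
  expect_lt(abs(median(errs) - 1), 0.15)
})

test_that("alpha update has its exact and degenerate limits", {
  # deterministic AR sequence: exact recovery of the coefficient
  K <- 30
  x <- 0.9^(0:K) * 5
  mom <- dyntrf:::empty_moments(K, 1L, 1L)
  for (i in 1:K) {
    mom$e0[i, 1] <- 1
    mom$e1[i, 1, ] <- x[i + 1] - 0.9 * x[i]
    mom$e2[[i]] <- matrix((x[i + 1] - 0.9 * x[i])^2, 1, 1)
    mom$x_prev[i, 1, ] <- x[i]
    mom$xx_prev[[i]] <- matrix(x[i]^2, 1, 1)
    mom$x_xprev[[i]] <- matrix(x[i + 1] * x[i], 1, 1)
  }
  model <- gm_noise_model(1, matrix(0, 1, 1), list(matrix(0.5, 1, 1)), W = 1)
  expect_equal(update_alpha(mom, model), 0.9, tolerance = 1e-8)
  # hand-built scalar moments against the direct ratio formula
  mom$x_xprev[[1]] <- matrix(3.3, 1, 1)
  g1 <- sum(x[1:K]^2) / 0.5
  g2 <- (sum(x[2:(K + 1)] * x[1:K]) - x[2] * x[1] + 3.3) / 0.5
  expect_equal(update_alpha(mom, model), min(g2 / g1, 1), tolerance = 1e-10)
  # equal quadratic and cross terms give exactly one
  mom2 <- dyntrf:::empty_moments(1L, 1L, 1L)
  mom2$e0[1, 1] <- 1; mom2$e1[1, 1, ] <- 0
  mom2$e2[[1]] <- matrix(1, 1, 1)
  mom2$x_prev[1, 1, ] <- 0
  mom2$xx_prev[[1]] <- matrix(2, 1, 1); mom2$x_xprev[[1]] <- matrix(2, 1, 1)
  expect_equal(update_alpha(mom2, model), 1)
})

test_that("inverse-gamma MAP update matches a numerical optimizer", {
  prior <- ig_prior(shape = 2.5, scale = 0.8, kappa = 7)
  w <- 40; q_ml <- 0.3
  q_hat <- apply_ig_map(q_ml, w, prior)
  obj <- function(q) -0.5 * w * (log(q) + q_ml / q) +
    7 * (-(2.5 + 1) * log(q) - 0.8 / q)
  q_opt <- optimize(obj, c(1e-4, 10), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(q_hat, q_opt, tolerance = 1e-6)
  # kappa -> 0 recovers the ML update; kappa -> Inf the prior mode
  expect_equal(apply_ig_map(q_ml, w, ig_prior(2.5, 0.8, 0)), q_ml)
  expect_equal(apply_ig_map(q_ml, w, ig_prior(2.5, 0.8, 1e12)),
               0.8 / 3.5, tolerance = 1e-6)
})

test_that("mean bounding solves the shrinkage quadratic and is idempotent", {
  # symmetric two-component case: closed-form shrink factor
  model <- gm_noise_model(c(0.5, 0.5), matrix(c(-2, 2), 1, 2),
                          list(matrix(0.1, 1, 1), matrix(0.1, 1, 1)), W = 1)
  q_ref <- 1
  b <- bound_means(model, q_ref)
  c_expect <- sqrt((q_ref - 0.1) / 4)   # between-variance 4 at +/-2
  expect_equal(b$means[1, ], c(-2, 2) * c_expect, tolerance = 1e-10)
  tot <- sum(b$probs * (0.1 + b$means[1, ]^2)) - sum(b$probs * b$means[1, ])^2
  expect_equal(tot, q_ref, tolerance = 1e-10)
  expect_equal(bound_means(b, q_ref), b, tolerance = 1e-12)
  # within-bound model unchanged; zero means unchanged for any bound
  expect_equal(bound_means(model, 10), model)
  m0 <- gm_noise_model(c(0.5, 0.5), matrix(0, 1, 2),
                       list(matrix(0.5, 1, 1), matrix(0.5, 1, 1)), W = 1)
  expect_equal(bound_means(m0, 0.01)$means, m0$means)
})

test_that("initialization strategies behave as documented", {
  set.seed(62)
  spec <- random_scalar_spec(60)
  model <- gm_noise_model(1, matrix(0, 1, 1), list(matrix(0.5, 1, 1)), W = 1)
  sim <- simulate_gm_ssm(spec, model)
  gfit <- gaussian_em_fit(spec, sim$y, list(max_iters = 30))
  # M = 1: both strategies return the Gaussian fit itself
  for (st in c("broad-random", "residual-gm-fit")) {
    m1 <- initialize_gm(st, 1, gfit, gfit$alpha, seed = 1)
    expect_equal(m1$covs[[1]], gfit$noise$cov)
  }
  # broad-random: exactly uniform probabilities, covariances = Gaussian fit
  m3 <- initialize_gm("broad-random", 3, gfit, gfit$alpha, seed = 1)
  expect_equal(m3$probs, rep(1 / 3, 3))
  for (m in 1:3) expect_equal(m3$covs[[m]], gfit$noise$cov)
  # residual fit on well-separated samples recovers the mixture weights
  set.seed(63)
  samp <- c(rnorm(300, -2, 0.2), rnorm(200, 2, 0.2))
  fit <- dyntrf:::gm_fit_samples(matrix(samp, ncol = 1), 2, seed = 4)
  expect_lt(max(abs(sort(fit$probs) - c(0.4, 0.6))), 0.05)
  expect_error(dyntrf:::gm_fit_samples(matrix(1), 2), "fewer samples")
})

test_that("single-component GM-SSM EM equals the Gaussian baseline trace", {
  set.seed(64)
  spec <- random_scalar_spec(40, t0 = 2)
  model <- gm_noise_model(1, matrix(0.2, 1, 1), list(matrix(0.4, 1, 1)), W = 1)
  sim <- simulate_gm_ssm(spec, model)
  cfg <- em_config(max_iters = 15, seed = 1)
  fit <- fit_gm_ssm(spec, sim$y, M = 1, W = 1, config = cfg)
  gfit <- gaussian_em_fit(spec, sim$y,
                          list(max_iters = 15, estimate_mean = TRUE))
  expect_equal(fit$logliks, gfit$logliks, tolerance = 1e-8)
  expect_equal(fit$model$covs[[1]], gfit$noise$cov, tolerance = 1e-8)
  expect_equal(fit$model$means[, 1], gfit$noise$mean, tolerance = 1e-8)
  expect_equal(fit$sigma2, gfit$sigma2, tolerance = 1e-8)
})

test_that("EM with the exact E-step backend has a monotone likelihood", {
  for (s in 1:5) {
    set.seed(800 + s)
    spec <- random_scalar_spec(6)
    model <- random_gm_model(2)
    sim <- simulate_gm_ssm(spec, model)
    cfg <- em_config(max_iters = 20, seed = s, e_step_backend = "exact")
    fit <- fit_gm_ssm(spec, sim$y, M = 2, W = 1, config = cfg)
    expect_gt(min(diff(fit$logliks)), -1e-8)
  }
})

test_that("GM-SSM EM recovers a well-separated two-component mixture", {
  res <- t(vapply(1:8, function(s) {
    inst <- recovery_instance(900 + s)
    cfg <- em_config(max_iters = 150, seed = s, init_strategy = "broad-random")
    fit <- fit_gm_ssm(inst$spec, inst$y, M = 2, W = 1, config = cfg)
    ord <- order(fit$model$means[1, ])
    c(p = fit$model$probs[ord][1], mu1 = fit$model$means[1, ord[1]],
      mu2 = fit$model$means[1, ord[2]])
  }, numeric(3)))
  expect_lt(median(abs(res[, "p"] - 0.5)), 0.1)
  expect_lt(median(abs(res[, "mu1"] + 1)), 0.2)
  expect_lt(median(abs(res[, "mu2"] - 1)), 0.2)
})

test_that("AIC selection handles singleton candidates and separated mixtures", {
  set.seed(65)
  inst <- recovery_instance(1)
  cfg <- em_config(max_iters = 40, seed = 1, init_strategy = "residual-gm-fit")
  sel1 <- aic_select(inst$spec, inst$y, Ms = 1, config = cfg)
  expect_equal(sel1$chosen_M, 1L)
  hits <- vapply(1:10, function(s) {
    inst <- recovery_instance(1100 + s)
    cfg <- em_config(max_iters = 40, seed = s,
                     init_strategy = "residual-gm-fit")
    sel <- aic_select(inst$spec, inst$y, Ms = 1:3, config = cfg)
    sel$chosen_M
  }, numeric(1))
  expect_gte(mean(hits == 2), 0.8)
  expect_error(aic_select(inst$spec, inst$y, Ms = integer(0)), "empty")
})

test_that("overestimating M still recovers a nearby mixture density", {
  # three-component scalar truth fitted with M = 3 and M = 5
  l1_dist <- function(fit, truth) {
    g <- seq(-4, 4, length.out = 800)
    df <- function(p, mu, s2) rowSums(vapply(seq_along(p), function(m)
      p[m] * dnorm(g, mu[m], sqrt(s2[m])), numeric(length(g))))
    d1 <- df(fit$model$probs, fit$model$means[1, ],
             vapply(fit$model$covs, function(C) C[1, 1], 1))
    d0 <- df(truth$probs, truth$means[1, ],
             vapply(truth$covs, function(C) C[1, 1], 1))
    mean(abs(d1 - d0)) * 8
  }
  ratios <- vapply(1:5, function(s) {
    set.seed(1200 + s)
    K <- 120
    spec <- state_space_spec(1, 0.9, rep(list(matrix(1, 1, 1)), K), 0.05)
    truth <- gm_noise_model(c(0.4, 0.3, 0.3), matrix(c(-1.5, 0, 1.5), 1, 3),
                            list(matrix(0.05, 1, 1), matrix(0.05, 1, 1),
                                 matrix(0.05, 1, 1)), W = 1)
    sim <- simulate_gm_ssm(spec, truth)
    cfg <- function(seed) em_config(max_iters = 80, seed = seed,
                                    init_strategy = "residual-gm-fit")
    f3 <- fit_gm_ssm(spec, sim$y, M = 3, W = 1, config = cfg(s))
    f5 <- fit_gm_ssm(spec, sim$y, M = 5, W = 1, config = cfg(s))
    l1_dist(f5, truth) / max(l1_dist(f3, truth), 1e-3)
  }, numeric(1))
  expect_lte(median(ratios), 2)
})

test_that("the SMC E-step backend drives a complete EM fit", {
  inst <- recovery_instance(42, K = 30)
  cfg <- em_config(max_iters = 4, seed = 1, e_step_backend = "smc", U = 400)
  fit <- fit_gm_ssm(inst$spec, inst$y, M = 2, W = 1, config = cfg)
  expect_true(all(is.finite(fit$logliks)))
  expect_equal(sum(fit$model$probs), 1, tolerance = 1e-10)
  expect_gt(fit$sigma2, 0)
  # deterministic given the seed
  fit2 <- fit_gm_ssm(inst$spec, inst$y, M = 2, W = 1, config = cfg)
  expect_identical(fit$logliks, fit2$logliks)
})
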