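# Shared fixture builders: random model instances and simulators used across
# the test files. Everything is generated in code under fixed seeds.

# Random scalar (d = 1) state-space spec with t0 samples per window.
random_scalar_spec <- function(N, t0 = 1L, alpha = NULL, sigma2 = NULL) {
  alpha <- alpha %||% runif(1, 0.5, 0.99)
  sigma2 <- sigma2 %||% runif(1, 0.2, 1)
  maps <- lapply(seq_len(N), function(n) matrix(runif(t0, 0.5, 1.5), t0, 1))
  state_space_spec(1L, alpha, maps, sigma2, x0_cov = matrix(runif(1, 1, 4), 1, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random GM noise model (diagonal covariances for d > 1).
random_gm_model <- function(M, d = 1L, W = 1L) {
  probs <- runif(M, 0.5, 1.5); probs <- probs / sum(probs)
  means <- matrix(rnorm(d * M, 0, 1), d, M)
  covs <- lapply(seq_len(M), function(m) diag(runif(d, 0.1, 0.8), d))
  gm_noise_model(probs, means, covs, W = W)
}

# Random small multivariate spec (for filter/smoother oracle checks).
random_spec <- function(N, d, t0) {
  maps <- lapply(seq_len(N), function(n) matrix(rnorm(t0 * d), t0, d))
  state_space_spec(d, runif(1, 0.3, 0.99), maps, runif(1, 0.3, 1.5),
                   x0_mean = rnorm(d, 0, 0.5), x0_cov = diag(runif(d, 0.5, 3), d))
}

# Draw observations from the GM-SSM generative model; returns states and
# the t0 x N observation matrix.
simulate_gm_ssm <- function(spec, model) {
  K <- spec$N %/% model$W
  d <- spec$d_x
  z <- sample.int(model$M, K, replace = TRUE, prob = model$probs)
  lab <- rep(z, each = model$W)
  x <- matrix(0, d, spec$N)
  xp <- spec$x0_mean + as.numeric(chol(spec$x0_cov)) * rnorm(d)
  if (d > 1) xp <- spec$x0_mean + as.numeric(t(chol(spec$x0_cov)) %*% rnorm(d))
  x0 <- xp
  for (n in seq_len(spec$N)) {
    w <- model$means[, lab[n]] +
      as.numeric(t(chol(model$covs[[lab[n]]])) %*% rnorm(d))
    xp <- spec$alpha * xp + w
    x[, n] <- xp
  }
  y <- matrix(0, spec$t0, spec$N)
  for (n in seq_len(spec$N))
    y[, n] <- as.numeric(spec$obs_maps[[n]] %*% x[, n]) +
      rnorm(spec$t0, 0, sqrt(spec$sigma2))
  list(x = x, x0 = x0, y = y, z = z)
}

# Scalar 2-component GM-SSM recovery instance: means +/-1, component sd
# `comp_sd` (separation 2/comp_sd standard deviations), informative
# observations (obs map = 1, small observation noise).
recovery_instance <- function(seed, K = 100L, comp_sd = 0.5, sigma2 = 0.05,
                              alpha = 0.95) {
  set.seed(seed)
  spec <- state_space_spec(1L, alpha, rep(list(matrix(1, 1, 1)), K), sigma2)
  model <- gm_noise_model(c(0.5, 0.5), matrix(c(-1, 1), 1, 2),
                          list(matrix(comp_sd^2, 1, 1),
                               matrix(comp_sd^2, 1, 1)), W = 1L)
  sim <- simulate_gm_ssm(spec, model)
  list(spec = spec, model = model, y = sim$y, x = sim$x, z = sim$z)
}

# Brute-force joint-Gaussian conditioning oracle: builds the joint normal of
# (x_0, x_{1:N}, y_{1:N}) for Gaussian process noise and conditions on y.
joint_gaussian_oracle <- function(spec, noise_mean, noise_cov, y) {
  N <- spec$N; d <- spec$d_x; t0 <- spec$t0; a <- spec$alpha
  nx <- (N + 1) * d
  # x = L e + c with e = (x0 - m0, w_1 - mu, ..., w_N - mu)
  L <- matrix(0, nx, nx)
  cvec <- numeric(nx)
  L[1:d, 1:d] <- diag(d)
  cvec[1:d] <- spec$x0_mean
  for (n in seq_len(N)) {
    rows <- n * d + 1:d
    prev <- (n - 1) * d + 1:d
    L[rows, ] <- a * L[prev, ]
    L[rows, rows] <- diag(d)
    cvec[rows] <- a * cvec[prev] + noise_mean
  }
  Se <- matrix(0, nx, nx)
  Se[1:d, 1:d] <- spec$x0_cov
  for (n in seq_len(N)) Se[n * d + 1:d, n * d + 1:d] <- noise_cov
  Sx <- L %*% Se %*% t(L)
  H <- matrix(0, N * t0, nx)
  for (n in seq_len(N)) H[(n - 1) * t0 + 1:t0, n * d + 1:d] <- spec$obs_maps[[n]]
  Sy <- H %*% Sx %*% t(H) + diag(spec$sigma2, N * t0)
  Sxy <- Sx %*% t(H)
  yv <- as.numeric(y)
  my <- as.numeric(H %*% cvec)
  post_mean <- cvec + as.numeric(Sxy %*% solve(Sy, yv - my))
  post_cov <- Sx - Sxy %*% solve(Sy, t(Sxy))
  ll <- -0.5 * (length(yv) * log(2 * pi) +
                  as.numeric(determinant(Sy)$modulus) +
                  sum((yv - my) * solve(Sy, yv - my)))
  list(mean = post_mean, cov = post_cov, loglik = ll, d = d)
}
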