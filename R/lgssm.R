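#' Specify a linear state-space model for windowed observations
#'
#' Defines the linear-Gaussian(-mixture) state-space model
#' \deqn{x_n = \alpha x_{n-1} + w_n, \qquad y_n = A_n x_n + v_n,}
#' where \eqn{x_n} is the state at window \eqn{n} (dimension `d_x`), each
#' observation window carries `t0` samples stacked into the vector
#' \eqn{y_n}, \eqn{A_n} is the per-window observation map (for TRF models the
#' composite of lagged stimulus features and the lag dictionary), and
#' \eqn{v_n \sim N(0, \sigma^2 I)} is i.i.d. observation noise. The process
#' noise \eqn{w_n} is supplied separately at inference time (a single
#' Gaussian, or a windowed Gaussian mixture; see [gm_noise_model()]).
#'
#' @param d_x State dimension.
#' @param alpha Transition coefficient in (0, 1]; the state evolution is the
#'   scalar-AR map \eqn{f(x) = \alpha x}.
#' @param obs_maps List of `N` observation matrices, each `t0 x d_x`.
#' @param sigma2 Observation noise variance (scalar, i.i.d. across samples).
#' @param x0_mean,x0_cov Initial-state prior \eqn{x_0 \sim N(m_0, P_0)}.
#'   Defaults: zero mean, `10 * diag(d_x)` (a broad prior; configurable
#'   because inference is mildly sensitive to it only for very short series).
#' @return An object of class `state_space_spec`.
#' @seealso [kalman_filter()], [rts_smoother()], [gaussian_em_fit()]
#' @export
state_space_spec <- function(d_x, alpha, obs_maps, sigma2,
                             x0_mean = rep(0, d_x),
                             x0_cov = 10 * diag(d_x)) {
  d_x <- as.integer(d_x)
  if (d_x < 1L) stop_dyntrf("d_x must be a positive integer")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop_dyntrf("alpha must be a scalar in (0, 1]")
  if (!is.numeric(sigma2) || sigma2 <= 0)
    stop_dyntrf("sigma2 must be a positive scalar")
  if (!is.list(obs_maps)) stop_dyntrf("obs_maps must be a list of matrices")
  obs_maps <- lapply(obs_maps, function(a) {
    a <- as.matrix(a)
    storage.mode(a) <- "double"
    a
  })
  N <- length(obs_maps)
  t0 <- if (N) nrow(obs_maps[[1]]) else 0L
  for (n in seq_len(N)) {
    a <- obs_maps[[n]]
    if (ncol(a) != d_x)
      stop_dyntrf("observation map for window %d has %d columns; expected d_x = %d",
                  n, ncol(a), d_x)
    if (nrow(a) != t0)
      stop_dyntrf("observation map for window %d has %d rows; expected t0 = %d",
                  n, nrow(a), t0)
  }
  x0_cov <- sym_psd(as.matrix(x0_cov))
  structure(
    list(d_x = d_x, alpha = alpha, obs_maps = obs_maps, sigma2 = sigma2,
         N = N, t0 = as.integer(t0),
         x0_mean = as.numeric(x0_mean), x0_cov = x0_cov),
    class = "state_space_spec")
}

#' @export
print.state_space_spec <- function(x, ...) {
  cat(sprintf("state_space_spec: d_x = %d, N = %d windows x t0 = %d samples, alpha = %.4g, sigma2 = %.4g\n",
              x$d_x, x$N, x$t0, x$alpha, x$sigma2))
  invisible(x)
}

#' Construct a Gaussian belief (mean and covariance)
#'
#' @param mean Mean vector.
#' @param cov Covariance matrix (symmetrized and eigenvalue-floored).
#' @return A list with elements `mean` and `cov`, class `gaussian_belief`.
#' @export
gaussian_belief <- function(mean, cov) {
  mean <- as.numeric(mean)
  cov <- sym_psd(as.matrix(cov))
  if (nrow(cov) != length(mean)) stop_dyntrf("mean/cov dimension mismatch")
  structure(list(mean = mean, cov = cov), class = "gaussian_belief")
}

# Normalize observations to a t0 x N matrix (columns = windows).
as_obs_matrix <- function(spec, observations) {
  if (is.list(observations)) observations <- do.call(cbind, observations)
  if (is.null(dim(observations))) {
    if (length(observations) != spec$N * spec$t0)
      stop_dyntrf("observations have length %d; expected N*t0 = %d",
                  length(observations), spec$N * spec$t0)
    observations <- matrix(observations, nrow = spec$t0)
  }
  observations <- as.matrix(observations)
  if (!identical(dim(observations), c(spec$t0, spec$N)) && spec$N > 0)
    stop_dyntrf("observations must be t0 x N = %d x %d", spec$t0, spec$N)
  observations
}

# One Kalman measurement update. Uses the information form when the window
# carries at least as many samples as state dimensions (cheaper, PSD by
# construction), otherwise a Joseph-form update. Returns the posterior belief
# and the predictive log-density of the window.
kf_update <- function(m_pred, P_pred, A, y, sigma2) {
  t0 <- nrow(A); d <- ncol(A)
  r <- y - as.numeric(A %*% m_pred)
  if (t0 >= d) {
    J <- crossprod(A) / sigma2
    b <- as.numeric(crossprod(A, r)) / sigma2
    Pchol <- chol_safe(P_pred)
    K <- chol2inv(Pchol) + J          # posterior precision
    Kchol <- chol_safe(K)
    cov <- chol2inv(Kchol)
    mean <- m_pred + as.numeric(cov %*% b)
    # log |sigma2 I + A P A'| = t0 log sigma2 + log|P| + log|P^-1 + J|
    logdet_S <- t0 * log(sigma2) + 2 * sum(log(diag(Pchol))) +
      2 * sum(log(diag(Kchol)))
    quad <- sum(r^2) / sigma2 - sum(b * as.numeric(cov %*% b))
    ll <- -0.5 * (t0 * log(2 * pi) + logdet_S + quad)
    list(mean = mean, cov = cov, loglik = ll)
  } else {
    S <- A %*% P_pred %*% t(A) + diag(sigma2, t0)
    Schol <- chol_safe(S)
    Kg <- P_pred %*% t(A) %*% chol2inv(Schol)
    mean <- m_pred + as.numeric(Kg %*% r)
    IKA <- diag(d) - Kg %*% A
    cov <- IKA %*% P_pred %*% t(IKA) + sigma2 * tcrossprod(Kg)  # Joseph form
    z <- forwardsolve(t(Schol), r)
    ll <- -0.5 * (t0 * log(2 * pi)) - sum(log(diag(Schol))) - 0.5 * sum(z^2)
    list(mean = mean, cov = (cov + t(cov)) / 2, loglik = ll)
  }
}

# Internal filter allowing per-window process-noise means/covariances
# (used by the label-sequence enumeration oracle). noise_means: d x N matrix;
# noise_covs: list of N covariance matrices.
kf_run <- function(spec, obs, noise_means, noise_covs) {
  N <- spec$N; d <- spec$d_x; a <- spec$alpha
  means <- matrix(0, d, N); covs <- vector("list", N)
  pmeans <- matrix(0, d, N); pcovs <- vector("list", N)
  ll <- 0
  m <- spec$x0_mean; P <- spec$x0_cov
  for (n in seq_len(N)) {
    mp <- a * m + noise_means[, n]
    Pp <- a^2 * P + noise_covs[[n]]
    up <- kf_update(mp, Pp, spec$obs_maps[[n]], obs[, n], spec$sigma2)
    pmeans[, n] <- mp; pcovs[[n]] <- Pp
    means[, n] <- up$mean; covs[[n]] <- up$cov
    ll <- ll + up$loglik
    m <- up$mean; P <- up$cov
  }
  structure(list(means = means, covs = covs, pred_means = pmeans,
                 pred_covs = pcovs, loglik = ll, spec = spec),
            class = "kfilter")
}

#' Kalman filter for a linear-Gaussian state-space model
#'
#' Runs the standard Kalman filter for the model defined by `spec` with
#' Gaussian process noise `noise` (mean and covariance shared across windows).
#' The measurement update uses the information form when a window carries at
#' least `d_x` samples and a Joseph-form update otherwise; both are exact.
#'
#' @param spec A [state_space_spec()].
#' @param observations Observations: a `t0 x N` matrix, a length-`N*t0`
#'   vector, or a list of `N` length-`t0` vectors.
#' @param noise A [gaussian_belief()] giving the process-noise mean and
#'   covariance.
#' @return An object of class `kfilter` with per-window filtered `means`
#'   (`d_x x N`), `covs`, one-step predicted moments, and `loglik`, the exact
#'   Gaussian data log-likelihood (sum of per-window predictive log-densities).
#' @export
kalman_filter <- function(spec, observations, noise) {
  stopifnot(inherits(spec, "state_space_spec"))
  if (inherits(noise, "gaussian_belief")) noise <- unclass(noise)
  if (length(noise$mean) != spec$d_x || nrow(noise$cov) != spec$d_x)
    stop_dyntrf("process-noise belief has dimension %d; expected %d",
                length(noise$mean), spec$d_x)
  Q <- sym_psd(as.matrix(noise$cov))
  if (spec$N == 0L)
    return(structure(list(means = matrix(0, spec$d_x, 0), covs = list(),
                          pred_means = matrix(0, spec$d_x, 0),
                          pred_covs = list(), loglik = 0, spec = spec),
                     class = "kfilter"))
  obs <- as_obs_matrix(spec, observations)
  out <- kf_run(spec, obs,
                matrix(noise$mean, spec$d_x, spec$N),
                rep(list(Q), spec$N))
  out$noise <- list(mean = as.numeric(noise$mean), cov = Q)
  out
}

# Shared RTS backward pass over a kfilter object (handles the per-window
# noise case as well). Returns smoothed moments for n = 0..N and lag-one
# cross-covariances Cov(x_n, x_{n-1} | Y) for n = 1..N.
rts_run <- function(filtered) {
  spec <- filtered$spec
  N <- spec$N; d <- spec$d_x; a <- spec$alpha
  sm <- matrix(0, d, N); sc <- vector("list", N)
  lag1 <- vector("list", N)
  if (N == 0L)
    return(list(means = sm, covs = sc, lag_one = lag1,
                x0_mean = spec$x0_mean, x0_cov = spec$x0_cov))
  sm[, N] <- filtered$means[, N]
  sc[[N]] <- filtered$covs[[N]]
  for (n in seq(N, 1)) {
    if (n > 1) {
      Pf <- filtered$covs[[n - 1]]
      mf <- filtered$means[, n - 1]
    } else {
      Pf <- spec$x0_cov
      mf <- spec$x0_mean
    }
    Pp <- filtered$pred_covs[[n]]
    J <- a * Pf %*% chol2inv(chol_safe(Pp))   # smoother gain J_{n-1}
    mn <- sm[, n]; Pn <- sc[[n]]
    prev_mean <- mf + as.numeric(J %*% (mn - filtered$pred_means[, n]))
    prev_cov <- sym_psd(Pf + J %*% (Pn - Pp) %*% t(J))
    lag1[[n]] <- Pn %*% t(J)                      # Cov(x_n, x_{n-1} | Y)
    if (n > 1) {
      sm[, n - 1] <- prev_mean
      sc[[n - 1]] <- prev_cov
    } else {
      x0_mean <- prev_mean
      x0_cov <- prev_cov
    }
  }
  list(means = sm, covs = sc, lag_one = lag1, x0_mean = x0_mean, x0_cov = x0_cov)
}

#' Rauch-Tung-Striebel fixed-interval smoother
#'
#' Backward pass over the output of [kalman_filter()], producing smoothed
#' means, covariances, and one-step cross-covariances
#' \eqn{Cov(x_n, x_{n-1} | y_{1:N})} as required by the EM sufficient
#' statistics. The initial state \eqn{x_0} is smoothed as well and stored in
#' the attributes `x0_mean`, `x0_cov`, and `lag_one_0`
#' (\eqn{Cov(x_1, x_0 | Y)}).
#'
#' @param spec The [state_space_spec()] used for filtering.
#' @param filtered A `kfilter` object from [kalman_filter()] on the same spec.
#' @return An object of class `smoothed_trajectory`: list with `means`
#'   (`d_x x N`), `covs` (list of `N`), `lag_one_covs` (list of `N - 1`
#'   matrices, entry `n` is \eqn{Cov(x_{n+1}, x_n | Y)}), and
#'   `log_likelihood`.
#' @export
rts_smoother <- function(spec, filtered) {
  stopifnot(inherits(spec, "state_space_spec"), inherits(filtered, "kfilter"))
  if (filtered$spec$N != spec$N || filtered$spec$d_x != spec$d_x)
    stop_dyntrf("filtered beliefs (N = %d) do not match spec (N = %d)",
                filtered$spec$N, spec$N)
  r <- rts_run(filtered)
  N <- spec$N
  out <- structure(
    list(means = r$means, covs = r$covs,
         lag_one_covs = if (N > 1) r$lag_one[2:N] else list(),
         log_likelihood = filtered$loglik),
    class = "smoothed_trajectory")
  attr(out, "x0_mean") <- r$x0_mean
  attr(out, "x0_cov") <- r$x0_cov
  attr(out, "lag_one_0") <- if (N >= 1) r$lag_one[[1]] else NULL
  out
}

#' Baseline EM for the linear-Gaussian state-space model
#'
#' Fits the Gaussian process-noise model by exact EM (Kalman filter + RTS
#' smoother E-step, closed-form M-step). Used as the single-component
#' baseline, as the initializer of the Gaussian-mixture EM, and as a
#' comparator. The per-iteration data log-likelihood is exact and
#' non-decreasing.
#'
#' @param spec A [state_space_spec()]. Its `alpha` and `sigma2` entries are
#'   the starting values when those parameters are estimated.
#' @param observations As in [kalman_filter()].
#' @param config List of options: `max_iters` (default 200), `tol` (relative
#'   log-likelihood change, default 1e-6), `estimate_mean` (default FALSE:
#'   the Gaussian baseline uses zero-mean process noise, which also guards
#'   the ill-identified dictionary directions from mean feedback through the
#'   near-unit transition coefficient),
#'   `estimate_sigma2` (default TRUE), `estimate_alpha` (default FALSE),
#'   `q_init` (initial process covariance, default identity), `var_floor`
#'   (diagonal floor, default 1e-10), `prior` (optional [ig_prior()] applied
#'   to the diagonal of Q as a MAP penalty).
#' @return List with `noise` (fitted [gaussian_belief()]), `sigma2`, `alpha`,
#'   `smoothed` (final [rts_smoother()] output), `logliks` (per-iteration
#'   exact log-likelihood at the start of each iteration), and `trace`
#'   (per-iteration parameter values).
#' @export
gaussian_em_fit <- function(spec, observations, config = list()) {
  stopifnot(inherits(spec, "state_space_spec"))
  if (spec$N < 2L) stop_dyntrf("Gaussian EM needs at least 2 windows")
  cfg <- modifyList(list(max_iters = 200L, tol = 1e-6, estimate_mean = FALSE,
                         estimate_sigma2 = TRUE, estimate_alpha = FALSE,
                         q_init = NULL, var_floor = 1e-10, prior = NULL,
                         diagonal = FALSE),
                    config)
  d <- spec$d_x; N <- spec$N
  obs <- as_obs_matrix(spec, observations)
  Q <- if (is.null(cfg$q_init)) diag(d) else sym_psd(as.matrix(cfg$q_init))
  mu <- rep(0, d)
  sigma2 <- spec$sigma2
  alpha <- spec$alpha
  logliks <- numeric(0)
  trace <- list()
  smoothed <- NULL
  floor_warned <- FALSE
  for (it in seq_len(cfg$max_iters)) {
    sp <- spec; sp$sigma2 <- sigma2; sp$alpha <- alpha
    kf <- kalman_filter(sp, obs, gaussian_belief(mu, Q))
    logliks <- c(logliks, kf$loglik)
    trace[[it]] <- list(mu = mu, Q = Q, sigma2 = sigma2, alpha = alpha,
                        loglik = kf$loglik)
    smoothed <- rts_smoother(sp, kf)
    # sufficient statistics over n = 1..N (x_0 smoothed under the prior)
    m <- cbind(attr(smoothed, "x0_mean"), smoothed$means)   # d x (N+1)
    covs <- c(list(attr(smoothed, "x0_cov")), smoothed$covs)
    lag1 <- c(list(attr(smoothed, "lag_one_0")), smoothed$lag_one_covs)
    S11 <- matrix(0, d, d); S00 <- matrix(0, d, d); S10 <- matrix(0, d, d)
    sum_prev <- rep(0, d)
    for (n in seq_len(N)) {
      S11 <- S11 + covs[[n + 1]] + tcrossprod(m[, n + 1])
      S00 <- S00 + covs[[n]] + tcrossprod(m[, n])
      S10 <- S10 + lag1[[n]] + tcrossprod(m[, n + 1], m[, n])
      sum_prev <- sum_prev + m[, n]
    }
    mu_new <- if (cfg$estimate_mean)
      (rowSums(m[, 2:(N + 1), drop = FALSE]) - alpha * sum_prev) / N
    else rep(0, d)
    Qn <- (S11 - alpha * S10 - alpha * t(S10) + alpha^2 * S00) / N -
      tcrossprod(mu_new)
    Qn <- sym_psd(Qn, cfg$var_floor)
    if (!is.null(cfg$prior)) {
      diag(Qn) <- apply_ig_map(diag(Qn), N, cfg$prior)
      Qn <- sym_psd(Qn, cfg$var_floor)
    }
    if (cfg$diagonal) Qn <- diag(pmax(diag(Qn), cfg$var_floor), d)
    if (any(diag(Qn) <= cfg$var_floor * 1.01) && !isTRUE(floor_warned)) {
      warning("process covariance diagonal clamped at the floor", call. = FALSE)
      floor_warned <- TRUE
    }
    if (cfg$estimate_sigma2) {
      sse <- 0
      for (n in seq_len(N)) {
        A <- spec$obs_maps[[n]]
        r <- obs[, n] - as.numeric(A %*% smoothed$means[, n])
        sse <- sse + sum(r^2) + sum((A %*% smoothed$covs[[n]]) * A)
      }
      sigma2 <- max(sse / (N * spec$t0), 1e-12)
    }
    if (cfg$estimate_alpha) {
      Qi <- chol2inv(chol(Qn))
      g1 <- sum(Qi * S00)
      g2 <- sum(Qi * t(S10)) - sum(mu_new * as.numeric(Qi %*% sum_prev))
      if (abs(g1) > 0) alpha <- min(max(g2 / g1, 1e-6), 1)
    }
    mu <- mu_new; Q <- Qn
    if (it > 1) {
      dll <- logliks[it] - logliks[it - 1]
      if (abs(dll) / (abs(logliks[it]) + 1e-12) < cfg$tol) break
    }
  }
  list(noise = gaussian_belief(mu, Q), sigma2 = sigma2, alpha = alpha,
       smoothed = smoothed, logliks = logliks, trace = trace)
}
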