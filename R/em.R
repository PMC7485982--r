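#' Inverse-gamma prior on the process-noise variance diagonal
#'
#' Conjugate inverse-gamma priors on the diagonal elements of the
#' process-noise covariance, added (scaled by the strength `kappa`) to the EM
#' surrogate Q-function as a MAP penalty. Bounds the dynamic range of the
#' process noise; without it, TRF estimates from real recordings tend to be
#' temporally erratic.
#'
#' @param shape,scale Per-dimension shape \eqn{\tilde\alpha_d > 0} and scale
#'   \eqn{\tilde\beta_d > 0} (recycled to the state dimension).
#' @param kappa Prior strength relative to the complete-data log-likelihood.
#'   Conventional defaults: `N` (number of state windows) for the Gaussian
#'   model and `N/M` for an `M`-component mixture, correcting for the number
#'   of components.
#' @return Object of class `ig_prior`.
#' @export
ig_prior <- function(shape, scale, kappa) {
  if (any(shape <= 0) || any(scale <= 0) || kappa < 0)
    stop_dyntrf("ig_prior needs shape > 0, scale > 0, kappa >= 0")
  structure(list(shape = as.numeric(shape), scale = as.numeric(scale),
                 kappa = kappa), class = "ig_prior")
}

#' Fit an inverse-gamma prior from empirical process-noise residuals
#'
#' Sets the prior so that its mode along each state dimension equals the
#' empirical variance of the supplied residual samples (typically
#' \eqn{\hat w_n = \hat x_n - \alpha \hat x_{n-1}} from a regularized RLS
#' fit), with a fixed shape.
#'
#' @param residuals `d x N` matrix of residual samples.
#' @param kappa Prior strength; see [ig_prior()].
#' @param shape Common shape parameter (default 2).
#' @return An [ig_prior()].
#' @export
ig_prior_from_residuals <- function(residuals, kappa, shape = 2) {
  residuals <- as.matrix(residuals)
  v <- apply(residuals, 1, stats::var)
  v <- pmax(v, 1e-12)
  ig_prior(shape = rep(shape, length(v)), scale = (shape + 1) * v,
           kappa = kappa)
}

#' MAP-regularized variance update under the inverse-gamma prior
#'
#' Maximizes the penalized M-step objective for each diagonal variance:
#' \deqn{q_d = \frac{w\, q_d^{ML} + 2\kappa \tilde\beta_d}
#'                  {w + 2\kappa(\tilde\alpha_d + 1)},}
#' where `w` is the effective weight of the update (`N` for the Gaussian
#' model; \eqn{W \sum_i \hat\epsilon_{i,m}} for mixture component `m`).
#' Reduces to the ML update as \eqn{\kappa \to 0} and to the prior mode
#' \eqn{\tilde\beta_d/(\tilde\alpha_d + 1)} as \eqn{\kappa \to \infty}.
#'
#' @param q_ml Vector of unpenalized (maximum-likelihood) variance updates.
#' @param weight Effective number of residual samples behind the update.
#' @param prior An [ig_prior()].
#' @return Vector of regularized variances.
#' @export
apply_ig_map <- function(q_ml, weight, prior) {
  stopifnot(inherits(prior, "ig_prior"))
  k <- prior$kappa
  (weight * q_ml + 2 * k * prior$scale) /
    (weight + 2 * k * (prior$shape + 1))
}

#' M-step parameter updates for the GM process-noise model
#'
#' Closed-form maximizers of the EM surrogate given the E-step moments:
#' \eqn{\hat p_m = K^{-1}\sum_i e_0(i,m)},
#' \eqn{\hat\mu_m = \sum_i e_1(i,m) / (W \sum_i e_0(i,m))},
#' \eqn{\hat\Sigma_m = \sum_i e_2(i,m)/(W\sum_i e_0(i,m)) -
#' \hat\mu_m\hat\mu_m^\top}. Covariances are symmetrized, floored, and
#' projected to diagonal form when the model is diagonal-only. A component
#' with vanishing responsibility keeps its previous mean/covariance with
#' probability set to its (zero) share, and a message is emitted.
#'
#' @param moments E-step moment set from [closed_form_e_step()],
#'   [mc_e_step()], or [enumerate_label_sequences()].
#' @param model The current [gm_noise_model()] (supplies `W`,
#'   `diagonal_only`, and fallback parameters for dead components).
#' @param prior Optional [ig_prior()] applied to the covariance diagonals.
#' @param var_floor Diagonal floor (default 1e-10).
#' @return The updated [gm_noise_model()].
#' @export
m_step_update <- function(moments, model, prior = NULL, var_floor = 1e-10) {
  M <- moments$M; d <- moments$d; K <- moments$K; W <- model$W
  probs <- colMeans(moments$e0)
  means <- model$means
  covs <- model$covs
  for (m in seq_len(M)) {
    denom <- W * sum(moments$e0[, m])
    if (denom <= 1e-12) {
      message(sprintf("mixture component %d received no responsibility; parameters frozen", m))
      probs[m] <- max(probs[m], 0)
      next
    }
    e1_m <- colSums(matrix(moments$e1[, m, ], nrow = K))
    mu <- e1_m / denom
    E2 <- matrix(0, d, d)
    for (i in seq_len(K)) E2 <- E2 + moments$e2[[mom_idx(moments, i, m)]]
    Sg <- E2 / denom - tcrossprod(mu)
    Sg <- sym_psd(Sg, var_floor)
    if (!is.null(prior)) {
      dg <- apply_ig_map(diag(Sg), denom, prior)
      if (model$diagonal_only) Sg <- diag(dg, d) else diag(Sg) <- dg
      Sg <- sym_psd(Sg, var_floor)
    }
    if (model$diagonal_only) Sg <- diag(pmax(diag(Sg), var_floor), d)
    means[, m] <- mu
    covs[[m]] <- Sg
  }
  probs <- pmax(probs, 0)
  probs <- probs / sum(probs)
  gm_noise_model(probs, means, covs, W = model$W,
                 diagonal_only = model$diagonal_only)
}

#' Observation-noise variance update
#'
#' EM update \eqn{\hat\sigma^2 = (Nt_0)^{-1}\sum_n E\{\|y_n - A_n x_n\|^2
#' \mid Y\}} using the posterior per-step first and second moments of the
#' smoothing distribution.
#'
#' @param spec The [state_space_spec()].
#' @param smoothing Either a `gm_smoothed` object ([two_filter_gm_smoother()]),
#'   the `smoothing` element of [enumerate_label_sequences()], a
#'   `particle_system`, or a [rts_smoother()] trajectory.
#' @param observations As in [kalman_filter()].
#' @return Updated positive variance.
#' @export
update_sigma2 <- function(spec, smoothing, observations) {
  obs <- as_obs_matrix(spec, observations)
  if (inherits(smoothing, "particle_system")) smoothing <- smoothed_moments(smoothing)
  if (inherits(smoothing, "smoothed_trajectory")) {
    means <- smoothing$means
    m2 <- lapply(seq_len(spec$N), function(n)
      smoothing$covs[[n]] + tcrossprod(means[, n]))
  } else {
    means <- smoothing$means
    m2 <- smoothing$second_moments
  }
  sse <- 0
  for (n in seq_len(spec$N)) {
    A <- spec$obs_maps[[n]]
    y <- obs[, n]
    cov_n <- m2[[n]] - tcrossprod(means[, n])
    r <- y - as.numeric(A %*% means[, n])
    sse <- sse + sum(r^2) + sum((A %*% cov_n) * A)
  }
  max(sse / (spec$N * spec$t0), 1e-12)
}

#' Transition-coefficient update
#'
#' Coordinate-descent update of the scalar AR coefficient: the ratio of the
#' inverse-covariance-weighted cross term to the quadratic term, aggregated
#' over label windows and components and clipped to (0, 1]. Evaluated at the
#' supplied (post-M-step) mixture parameters.
#'
#' @param moments E-step moment set.
#' @param model The (updated) [gm_noise_model()].
#' @param fallback Value returned (with a message) when the quadratic term
#'   vanishes.
#' @return Scalar in (0, 1].
#' @export
update_alpha <- function(moments, model, fallback = NA_real_) {
  g <- moments_g(moments, model)
  g1 <- sum(g$g1); g2 <- sum(g$g2)
  if (abs(g1) <= 1e-300) {
    message("alpha update skipped: zero quadratic term")
    return(fallback)
  }
  min(max(g2 / g1, 1e-6), 1)
}

#' Bound mixture means so the mixture variance respects a reference
#'
#' If the total mixture variance along dimension `d`,
#' \eqn{\sum_m p_m(\Sigma_{m,dd} + \mu_{m,d}^2) - (\sum_m p_m \mu_{m,d})^2},
#' exceeds the reference `q_ref[d]` (typically the Gaussian-SSM estimate),
#' all component means along that dimension are shrunk toward their weighted
#' mean by the unique factor restoring equality. Already-bounded dimensions
#' are untouched (the operation is idempotent); if even the within-component
#' variance exceeds the bound, the means collapse to their weighted mean.
#'
#' @param model A [gm_noise_model()].
#' @param q_ref Reference variance per dimension.
#' @return The bounded [gm_noise_model()].
#' @export
bound_means <- function(model, q_ref) {
  d <- nrow(model$means)
  q_ref <- rep_len(as.numeric(q_ref), d)
  means <- model$means
  p <- model$probs
  for (dd in seq_len(d)) {
    mu <- means[dd, ]
    within <- sum(p * vapply(model$covs, function(C) C[dd, dd], numeric(1)))
    mbar <- sum(p * mu)
    between <- sum(p * (mu - mbar)^2)
    total <- within + between
    if (total <= q_ref[dd] || between <= 1e-300) next
    c2 <- (q_ref[dd] - within) / between
    cshrink <- if (c2 > 0) sqrt(c2) else 0
    means[dd, ] <- mbar + cshrink * (mu - mbar)
  }
  gm_noise_model(model$probs, means, model$covs, W = model$W,
                 diagonal_only = model$diagonal_only)
}

# Seeded sample-space Gaussian-mixture ML fit (delegated to mclust).
# Used for the residual-fit initializer and the oracle GM fit.
gm_fit_samples <- function(samples, M, diagonal = TRUE, seed = 1L) {
  samples <- as.matrix(samples)            # rows = samples
  d <- ncol(samples)
  if (nrow(samples) < M)
    stop_dyntrf("fewer samples (%d) than mixture components (%d)", nrow(samples), M)
  model_names <- if (d == 1L) "V" else if (diagonal) "VVI" else "VVV"
  mclustBIC <- mclust::mclustBIC   # Mclust() resolves this in the caller frame
  fit <- with_seed(seed, suppressWarnings(
    mclust::Mclust(samples, G = M, modelNames = model_names, verbose = FALSE)))
  if (is.null(fit)) stop_dyntrf("sample-space GM fit failed for M = %d", M)
  p <- as.numeric(fit$parameters$pro)
  mu <- matrix(fit$parameters$mean, nrow = d)
  if (d == 1L) {
    vars <- fit$parameters$variance$sigmasq
    if (length(vars) == 1L) vars <- rep(vars, M)
    covs <- lapply(vars, function(v) matrix(v, 1, 1))
  } else {
    sig <- fit$parameters$variance$sigma
    covs <- lapply(seq_len(M), function(m) sig[, , m])
  }
  list(probs = p, means = mu, covs = covs, loglik = fit$loglik, mclust = fit)
}

#' Initialize the GM process-noise model
#'
#' Two strategies: `"broad-random"` sets uniform probabilities, small random
#' means, and every covariance equal to the Gaussian-SSM process-noise
#' estimate (a deliberately broad start, narrowed by EM); `"residual-gm-fit"`
#' fits a sample-space Gaussian mixture to the empirical process-noise
#' residuals \eqn{\hat w_n = \hat x^{(s)}_n - \alpha \hat x^{(s)}_{n-1}} of
#' the Gaussian-SSM smoothed states (faster convergence, the preferred start
#' for low-SNR data).
#'
#' @param strategy `"broad-random"` or `"residual-gm-fit"`.
#' @param M Number of mixture components.
#' @param gaussian_fit A [gaussian_em_fit()] result.
#' @param alpha Transition coefficient used to form residuals.
#' @param W Label-window length for the returned model.
#' @param diagonal_only Passed to [gm_noise_model()].
#' @param seed RNG seed (random means; sample-space fit).
#' @return A [gm_noise_model()].
#' @export
initialize_gm <- function(strategy = c("broad-random", "residual-gm-fit"),
                          M, gaussian_fit, alpha, W = 1L,
                          diagonal_only = FALSE, seed = 1L) {
  strategy <- match.arg(strategy)
  Q <- gaussian_fit$noise$cov
  d <- nrow(Q)
  if (M == 1L) {
    return(gm_noise_model(1, matrix(gaussian_fit$noise$mean, d, 1), list(Q),
                          W = W, diagonal_only = diagonal_only))
  }
  if (strategy == "broad-random") {
    # mean spread of half the broad covariance scale: still "close to zero"
    # on the scale of the component spread, but enough to break the
    # symmetric EM fixed point of identical components
    sd0 <- 0.5 * sqrt(pmax(diag(Q), 1e-12))
    means <- with_seed(seed, matrix(stats::rnorm(d * M, 0, sd0), d, M))
    gm_noise_model(rep(1 / M, M), means, rep(list(Q), M), W = W,
                   diagonal_only = diagonal_only)
  } else {
    sm <- gaussian_fit$smoothed
    X <- cbind(attr(sm, "x0_mean"), sm$means)
    resid <- X[, -1, drop = FALSE] - alpha * X[, -ncol(X), drop = FALSE]
    fit <- gm_fit_samples(t(resid), M, diagonal = diagonal_only, seed = seed)
    gm_noise_model(fit$probs, fit$means, fit$covs, W = W,
                   diagonal_only = diagonal_only)
  }
}

#' Configuration for the GM process-noise EM
#'
#' @param max_iters Maximum EM iterations (default 200).
#' @param tol Relative change in approximate log-likelihood below which EM
#'   stops (default 1e-6).
#' @param init_strategy Initialization strategy; see [initialize_gm()].
#' @param estimate_sigma2,estimate_alpha Whether the observation-noise
#'   variance and transition coefficient are re-estimated each iteration.
#' @param caps Reduction caps `(gamma_f, gamma_b, gamma_s)` for the
#'   closed-form backend; default `NULL` sets all three to `M`.
#' @param e_step_backend `"closed-form"`, `"smc"`, or `"exact"` (enumeration;
#'   tiny instances only).
#' @param U Particle count for the SMC backend (default 2000).
#' @param seed Seed for every stochastic ingredient (initialization, SMC).
#' @param var_floor Diagonal covariance floor.
#' @param bound_means Whether mixture means are bounded each iteration so
#'   the mixture variance does not exceed the Gaussian-SSM estimate.
#' @param diagonal_only Diagonal mixture covariances (the TRF default).
#' @param q_init Initial process covariance of the Gaussian pre-fit.
#' @param gauss_iters Iteration cap of the Gaussian pre-fit (default 100).
#' @param init_model Optional explicit [gm_noise_model()] start, overriding
#'   `init_strategy`.
#' @return A list of class `em_config`.
#' @export
em_config <- function(max_iters = 200L, tol = 1e-6,
                      init_strategy = "broad-random",
                      estimate_sigma2 = TRUE, estimate_alpha = FALSE,
                      caps = NULL,
                      e_step_backend = c("closed-form", "smc", "exact"),
                      U = 2000L, seed = 1L, var_floor = 1e-10,
                      bound_means = FALSE, diagonal_only = FALSE,
                      q_init = NULL, gauss_iters = 100L, init_model = NULL) {
  e_step_backend <- match.arg(e_step_backend)
  structure(list(max_iters = max_iters, tol = tol,
                 init_strategy = init_strategy,
                 estimate_sigma2 = estimate_sigma2,
                 estimate_alpha = estimate_alpha, caps = caps,
                 e_step_backend = e_step_backend, U = U, seed = seed,
                 var_floor = var_floor, bound_means = bound_means,
                 diagonal_only = diagonal_only, q_init = q_init,
                 gauss_iters = gauss_iters, init_model = init_model),
            class = "em_config")
}

#' Fit the state-space model with GM process noise by EM
#'
#' Alternates the configured E-step backend (closed-form two-filter
#' Gaussian-sum smoothing, SMC particle smoothing, or exact enumeration on
#' tiny instances) with the closed-form M-step, optionally applying the
#' inverse-gamma MAP penalty and mean bounding, until the approximate
#' log-likelihood stabilizes. With `M = 1` and the default initialization
#' this reproduces the Gaussian baseline [gaussian_em_fit()] iteration for
#' iteration (a single-component mixture EM *is* Gaussian EM, so no Gaussian
#' pre-fit is run in that case).
#'
#' @param spec A [state_space_spec()]; its `sigma2`/`alpha` are starting
#'   values when estimated.
#' @param observations As in [kalman_filter()].
#' @param M Number of mixture components.
#' @param W Label-window length (one mixture label per `W` state steps).
#' @param config An [em_config()].
#' @param prior Optional [ig_prior()].
#' @return Object of class `gm_ssm_fit`: `model`, `sigma2`, `alpha`,
#'   `smoothing` (final E-step posterior), `logliks` (per-iteration
#'   approximate log-likelihood at the start of each iteration), `trace`
#'   (per-iteration parameters), `gaussian_fit` (NULL for the `M = 1`
#'   broad-random path), `config`.
#' @export
fit_gm_ssm <- function(spec, observations, M, W = 1L, config = em_config(),
                       prior = NULL) {
  stopifnot(inherits(spec, "state_space_spec"))
  if (M < 1L) stop_dyntrf("M must be >= 1")
  if (spec$N %% W != 0L)
    stop_dyntrf("N = %d not divisible by W = %d", spec$N, W)
  cfg <- config
  obs <- as_obs_matrix(spec, observations)
  d <- spec$d_x
  gcfg <- list(max_iters = cfg$gauss_iters, tol = cfg$tol,
               estimate_mean = FALSE, estimate_sigma2 = cfg$estimate_sigma2,
               estimate_alpha = cfg$estimate_alpha, q_init = cfg$q_init,
               var_floor = cfg$var_floor, diagonal = cfg$diagonal_only)
  if (!is.null(prior)) {
    # the Gaussian pre-fit takes the same prior at the Gaussian-case
    # strength (kappa scaled by M, undoing the N/M mixture correction)
    gprior <- prior
    gprior$kappa <- prior$kappa * M
    gcfg$prior <- gprior
  }
  gfit <- NULL
  q_ref <- NULL
  if (!is.null(cfg$init_model)) {
    model <- cfg$init_model
    if (model$W != W) stop_dyntrf("init_model W mismatch")
  } else if (M == 1L && cfg$init_strategy == "broad-random") {
    Q0 <- if (is.null(cfg$q_init)) diag(d) else sym_psd(as.matrix(cfg$q_init))
    if (cfg$diagonal_only) Q0 <- diag(diag(Q0), d)
    model <- gm_noise_model(1, matrix(0, d, 1), list(Q0), W = W,
                            diagonal_only = cfg$diagonal_only)
  } else {
    gfit <- gaussian_em_fit(spec, obs, gcfg)
    q_ref <- diag(gfit$noise$cov)
    sp_g <- spec; sp_g$sigma2 <- gfit$sigma2; sp_g$alpha <- gfit$alpha
    model <- initialize_gm(cfg$init_strategy, M, gfit, gfit$alpha, W = W,
                           diagonal_only = cfg$diagonal_only, seed = cfg$seed)
    spec <- sp_g
  }
  caps <- cfg$caps %||% rep(M, 3)
  sigma2 <- spec$sigma2
  alpha <- spec$alpha
  logliks <- numeric(0)
  trace <- list()
  smoothing <- NULL
  for (it in seq_len(cfg$max_iters)) {
    sp <- spec; sp$sigma2 <- sigma2; sp$alpha <- alpha
    mom <- switch(cfg$e_step_backend,
      "closed-form" = closed_form_e_step(sp, model, obs, caps),
      "smc" = {
        ps <- particle_smoother(sp, model, obs, U = cfg$U,
                                seed = cfg$seed + it)
        m <- mc_e_step(ps, model, sp)
        sm <- smoothed_moments(ps)
        sm$particles <- ps
        attr(m, "smoothing") <- sm
        m
      },
      "exact" = {
        en <- enumerate_label_sequences(sp, model, obs)
        m <- en$moments
        attr(m, "smoothing") <- en$smoothing
        m
      })
    smoothing <- attr(mom, "smoothing")
    logliks <- c(logliks, mom$approx_loglik)
    trace[[it]] <- list(model = model, sigma2 = sigma2, alpha = alpha,
                        loglik = mom$approx_loglik)
    model_new <- m_step_update(mom, model, prior = prior,
                               var_floor = cfg$var_floor)
    if (cfg$bound_means && !is.null(q_ref))
      model_new <- bound_means(model_new, q_ref)
    if (cfg$estimate_sigma2)
      sigma2 <- update_sigma2(sp, smoothing, obs)
    if (cfg$estimate_alpha) {
      a_new <- update_alpha(mom, model_new, fallback = alpha)
      alpha <- a_new
    }
    model <- model_new
    if (it > 1) {
      dll <- logliks[it] - logliks[it - 1]
      if (abs(dll) / (abs(logliks[it]) + 1e-12) < cfg$tol) break
    }
  }
  structure(list(model = model, sigma2 = sigma2, alpha = alpha,
                 smoothing = smoothing, logliks = logliks, trace = trace,
                 gaussian_fit = gfit, config = cfg, M = M, W = W),
            class = "gm_ssm_fit")
}

#' @export
print.gm_ssm_fit <- function(x, ...) {
  cat(sprintf("gm_ssm_fit: M = %d, W = %d, %d EM iterations, final approx loglik %.3f\n",
              x$M, x$W, length(x$logliks), utils::tail(x$logliks, 1)))
  print(x$model)
  cat(sprintf("  sigma2 = %.4g, alpha = %.4g\n", x$sigma2, x$alpha))
  invisible(x)
}

#' Select the number of mixture components by AIC
#'
#' Fits the model for each candidate `M` and scores
#' \eqn{AIC = 2k - 2\,\hat\ell} with \eqn{\hat\ell} the final approximate
#' log-likelihood and `k` the free-parameter count of the mixture:
#' `M - 1` probabilities, `M * d` means, `M * d` variances for diagonal
#' covariances (`M * d(d+1)/2` for full), plus one for each of
#' \eqn{\sigma^2} and \eqn{\alpha} when estimated. Ties break toward the
#' smaller `M`.
#'
#' @inheritParams fit_gm_ssm
#' @param Ms Candidate component counts.
#' @return List with `chosen_M`, `table` (data frame of `M`, `k`, `loglik`,
#'   `aic`), and `fits` (the per-candidate [fit_gm_ssm()] results).
#' @export
aic_select <- function(spec, observations, Ms, W = 1L, config = em_config(),
                       prior = NULL) {
  if (!length(Ms)) stop_dyntrf("empty candidate set for M")
  Ms <- sort(unique(as.integer(Ms)))
  d <- spec$d_x
  fits <- list(); rows <- list()
  for (M in Ms) {
    fit <- fit_gm_ssm(spec, observations, M, W = W, config = config,
                      prior = prior)
    cov_k <- if (config$diagonal_only) M * d else M * d * (d + 1) / 2
    k <- (M - 1) + M * d + cov_k +
      as.integer(config$estimate_sigma2) + as.integer(config$estimate_alpha)
    ll <- utils::tail(fit$logliks, 1)
    rows[[as.character(M)]] <- data.frame(M = M, k = k, loglik = ll,
                                          aic = 2 * k - 2 * ll)
    fits[[as.character(M)]] <- fit
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  best <- tab$M[which.min(tab$aic)]   # which.min takes the first (smallest M) tie
  list(chosen_M = best, table = tab, fits = fits)
}
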