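#' Gaussian lag dictionary for TRF representation
#'
#' Builds the lag-domain dictionary `G` whose columns are unnormalized
#' Gaussian kernels \eqn{\exp(-( \ell - c_d)^2 / (2 v))} sampled on the lag
#' grid \eqn{\ell = 0, 1/F_s, \ldots, (L-1)/F_s}, with centers spaced
#' `center_spacing_s` apart from lag 0. TRFs are represented as
#' \eqn{\tau = G x}; for two speakers the block-diagonal
#' \eqn{\tilde G = diag(G, G)} applies per-speaker states. Columns are not
#' normalized: any global scale is absorbed by the states.
#'
#' @param F_s Sampling rate (Hz).
#' @param trf_length_s TRF length in seconds (`L = trf_length_s * F_s`
#'   samples).
#' @param center_spacing_s Spacing of atom centers in seconds.
#' @param atom_variance_s2 Variance of the Gaussian atoms in seconds squared.
#' @return Object of class `trf_dictionary`: `G` (`L x D`), `Gtilde`
#'   (`2L x 2D`), `atom_centers` (seconds), `lags` (seconds), `F_s`.
#' @export
build_dictionary <- function(F_s, trf_length_s, center_spacing_s,
                             atom_variance_s2) {
  L <- round(trf_length_s * F_s)
  if (L < 1L) stop_dyntrf("TRF length shorter than one sample")
  lags <- (seq_len(L) - 1) / F_s
  if (center_spacing_s > trf_length_s + 1e-9)
    stop_dyntrf("atom spacing produces no atoms beyond lag zero")
  centers <- seq(0, trf_length_s - center_spacing_s + 1e-9,
                 by = center_spacing_s)
  G <- vapply(centers, function(c0) exp(-(lags - c0)^2 / (2 * atom_variance_s2)),
              numeric(L))
  G <- matrix(G, nrow = L)
  D <- ncol(G)
  Gtilde <- rbind(cbind(G, matrix(0, L, D)), cbind(matrix(0, L, D), G))
  structure(list(G = G, Gtilde = Gtilde, atom_centers = centers, lags = lags,
                 F_s = F_s, L = L, D = D,
                 atom_variance_s2 = atom_variance_s2),
            class = "trf_dictionary")
}

#' Lag-embedded stimulus design for the two-speaker TRF model
#'
#' Builds the lagged feature vectors \eqn{s_t = [s_t^{(1)}; s_t^{(2)}]}
#' (each \eqn{s_t^{(q)} = [s_t, \ldots, s_{t-L+1}]^\top}, zero-padded before
#' `t = L`) and the per-window design matrices \eqn{S_n} stacking the columns
#' of samples \eqn{(n-1)t_0 + 1, \ldots, n t_0}. The window-`n` response
#' model is \eqn{y_n = S_n^\top \tilde G x_n + v_n}.
#'
#' @param envelopes `T x 2` matrix (or list of two vectors) of per-speaker
#'   stimulus features, one value per sample.
#' @param F_s Sampling rate (Hz).
#' @param L TRF length in samples.
#' @param t0 Samples per state window; a trailing partial window is truncated
#'   with a warning.
#' @return Object of class `speech_design`: `S` (list of `N` matrices
#'   `2L x t0`), `N`, `t0`, `L`, `F_s`, `T_used`.
#' @export
build_design <- function(envelopes, F_s, L, t0) {
  if (is.list(envelopes)) envelopes <- do.call(cbind, envelopes)
  envelopes <- as.matrix(envelopes)
  if (ncol(envelopes) != 2L) stop_dyntrf("expected two speaker envelopes")
  Tn <- nrow(envelopes)
  N <- Tn %/% t0
  if (Tn %% t0 != 0L) {
    warning(sprintf("truncating %d trailing samples (T not divisible by t0)",
                    Tn %% t0), call. = FALSE)
  }
  if (N < 1L) stop_dyntrf("fewer samples than one window")
  lagmat <- function(e) {
    out <- matrix(0, L, Tn)
    for (l in seq_len(L)) {
      idx <- seq_len(Tn) - (l - 1L)
      ok <- idx >= 1L
      out[l, ok] <- e[idx[ok]]
    }
    out
  }
  S_full <- rbind(lagmat(envelopes[, 1]), lagmat(envelopes[, 2]))  # 2L x T
  S <- lapply(seq_len(N), function(n)
    S_full[, ((n - 1L) * t0 + 1L):(n * t0), drop = FALSE])
  structure(list(S = S, N = N, t0 = as.integer(t0), L = as.integer(L),
                 F_s = F_s, T_used = N * t0),
            class = "speech_design")
}

# Observation maps A_n = S_n' Gtilde for a design/dictionary pair.
design_obs_maps <- function(design, dict) {
  lapply(design$S, function(S) crossprod(S, dict$Gtilde))
}

#' Container for per-speaker TRF estimates over time
#'
#' @param states `d x N` matrix of dictionary coefficients over windows.
#' @param dict The [trf_dictionary()][build_dictionary()] used.
#' @param t0 Samples per window.
#' @param estimator Identifier of the producing estimator.
#' @return Object of class `trf_series` with `tau1`/`tau2` (`L x N`
#'   per-speaker kernels, \eqn{\tau_n = \tilde G x_n}), `states`, `lags`,
#'   `time_s` (window centers), and provenance fields.
#' @export
trf_series <- function(states, dict, t0, estimator = "unknown") {
  states <- as.matrix(states)
  if (nrow(states) != 2L * dict$D)
    stop_dyntrf("states must have 2D = %d rows", 2L * dict$D)
  tau <- dict$Gtilde %*% states
  N <- ncol(states)
  structure(list(tau1 = tau[seq_len(dict$L), , drop = FALSE],
                 tau2 = tau[dict$L + seq_len(dict$L), , drop = FALSE],
                 states = states, lags = dict$lags,
                 time_s = (seq_len(N) - 0.5) * t0 / dict$F_s,
                 t0 = t0, F_s = dict$F_s, estimator = estimator),
            class = "trf_series")
}

#' @export
print.trf_series <- function(x, ...) {
  cat(sprintf("trf_series [%s]: %d lags x %d windows, F_s = %g Hz\n",
              x$estimator, length(x$lags), ncol(x$tau1), x$F_s))
  invisible(x)
}

#' Dynamic TRF estimation via state-space smoothing
#'
#' Assembles the state-space spec with observation maps
#' \eqn{A_n = S_n^\top \tilde G}, fits the process-noise model by EM
#' ([gaussian_em_fit()] for the Gaussian backend; [fit_gm_ssm()] for the GM
#' backend), and maps the smoothed states through the dictionary:
#' \eqn{\hat\tau_n = \tilde G \hat x_{n|N}}.
#'
#' @param design A [build_design()] result.
#' @param response Numeric response vector of length `N * t0`.
#' @param dict The dictionary.
#' @param backend `"gaussian"` or `"gm"`.
#' @param M,W Mixture size and label-window length for the GM backend.
#' @param alpha,sigma2 Transition coefficient and initial observation-noise
#'   variance.
#' @param config An [em_config()].
#' @param prior Optional [ig_prior()].
#' @param estimate_mean Whether the Gaussian backend estimates the
#'   process-noise mean (TRUE mirrors the single-component mixture EM;
#'   FALSE is the classical zero-mean Gaussian baseline).
#' @return List with `trf` (a [trf_series()]), `fit` (backend fit object),
#'   and `spec`.
#' @export
fit_trf_ssm <- function(design, response, dict,
                        backend = c("gaussian", "gm"), M = 1L, W = 1L,
                        alpha = 0.99, sigma2 = 1, config = em_config(),
                        prior = NULL, estimate_mean = TRUE) {
  backend <- match.arg(backend)
  spec <- state_space_spec(2L * dict$D, alpha, design_obs_maps(design, dict),
                           sigma2)
  y <- as.numeric(response)[seq_len(design$T_used)]
  if (backend == "gaussian") {
    gcfg <- list(max_iters = config$max_iters, tol = config$tol,
                 estimate_mean = estimate_mean,
                 estimate_sigma2 = config$estimate_sigma2,
                 estimate_alpha = config$estimate_alpha, q_init = config$q_init,
                 var_floor = config$var_floor, prior = prior)
    if (config$diagonal_only) gcfg$diagonal <- TRUE
    fit <- gaussian_em_fit(spec, y, gcfg)
    states <- fit$smoothed$means
    est <- "gaussian-ssm"
  } else {
    fit <- fit_gm_ssm(spec, y, M = M, W = W, config = config, prior = prior)
    states <- fit$smoothing$means
    est <- sprintf("gm-ssm(M=%d)", M)
  }
  list(trf = trf_series(states, dict, design$t0, estimator = est),
       fit = fit, spec = spec)
}

#' Regularized recursive least squares TRF estimation
#'
#' Per window `n`, minimizes
#' \eqn{\sum_{i \le n} \lambda^{n-i} \|y_i - S_i^\top \tilde G x\|^2 +
#' \gamma h(x)} with forgetting factor \eqn{\lambda \in [0, 1)} and an
#' \eqn{\ell_2} or \eqn{\ell_1} penalty. The \eqn{\ell_2} path uses
#' recursively updated normal equations; the \eqn{\ell_1} path solves each
#' window by coordinate descent. Estimates are causal (filtering) by design.
#' With `lambda = 0` the fit reduces to per-window (regularized) least
#' squares, the surrogate used by the MSAR benchmark.
#'
#' @inheritParams fit_trf_ssm
#' @param lambda Forgetting factor in [0, 1).
#' @param gamma Penalty weight (>= 0).
#' @param penalty `"l2"` or `"l1"`.
#' @return A [trf_series()].
#' @export
rls_fit <- function(design, response, dict, lambda, gamma = 0,
                    penalty = c("l2", "l1")) {
  penalty <- match.arg(penalty)
  if (lambda < 0 || lambda >= 1) stop_dyntrf("lambda must be in [0, 1)")
  maps <- design_obs_maps(design, dict)
  y <- matrix(as.numeric(response)[seq_len(design$T_used)],
              nrow = design$t0)
  p <- 2L * dict$D
  Phi <- matrix(0, p, p)
  beta <- rep(0, p)
  states <- matrix(0, p, design$N)
  for (n in seq_len(design$N)) {
    B <- maps[[n]]
    Phi <- lambda * Phi + crossprod(B)
    beta <- lambda * beta + as.numeric(crossprod(B, y[, n]))
    if (penalty == "l2") {
      A <- Phi + diag(gamma, p)
      x <- tryCatch(solve_pd(sym_psd(A, 0), beta), error = function(e) NULL)
      if (is.null(x))
        stop_dyntrf("singular regularized system at window %d; increase gamma", n)
      states[, n] <- x
    } else {
      states[, n] <- lasso_cd(Phi, beta, gamma,
                              x0 = if (n > 1) states[, n - 1] else rep(0, p))
    }
  }
  trf_series(states, dict, design$t0,
             estimator = sprintf("rls(lambda=%.3g,%s)", lambda, penalty))
}

# Coordinate descent for 0.5 x'Phi x - beta'x + gamma ||x||_1.
lasso_cd <- function(Phi, beta, gamma, x0, max_iter = 500L, tol = 1e-8) {
  p <- length(beta)
  x <- x0
  dPhi <- pmax(diag(Phi), 1e-12)
  for (it in seq_len(max_iter)) {
    x_old <- x
    for (j in seq_len(p)) {
      r <- beta[j] - sum(Phi[j, ] * x) + Phi[j, j] * x[j]
      x[j] <- sign(r) * max(abs(r) - gamma, 0) / dPhi[j]
    }
    if (max(abs(x - x_old)) < tol * (1 + max(abs(x)))) break
  }
  x
}

#' Convert an effective estimation length to an RLS forgetting factor
#'
#' The forgetting factor whose geometric window has the requested effective
#' length: \eqn{\lambda = 1 - t_0 / (F_s \cdot \mathrm{length})}, i.e. the
#' weight sum \eqn{1/(1-\lambda)} spans `length_s` seconds of windows.
#'
#' @param length_s Effective estimation length in seconds.
#' @param t0 Samples per window.
#' @param F_s Sampling rate (Hz).
#' @return Forgetting factor in [0, 1).
#' @export
effective_length_to_lambda <- function(length_s, t0, F_s) {
  lam <- 1 - t0 / (F_s * length_s)
  min(max(lam, 0), 1 - 1e-6)
}

#' Choose the RLS penalty weight by two-fold cross-validation
#'
#' Splits the trial into two contiguous halves; for each direction, fits RLS
#' on one half and scores the predictive mean squared error of the final
#' estimate on the other half's windows; the two directions are averaged and
#' the `gamma` with the lowest score wins, ties going to the larger (more
#' regularized) value.
#'
#' @inheritParams rls_fit
#' @param gammas Candidate penalty weights.
#' @return List with `gamma` (the winner) and `cv_mse` (per-candidate score).
#' @export
choose_gamma <- function(design, response, dict, lambda, gammas,
                         penalty = "l2") {
  N <- design$N
  if (N < 4L) stop_dyntrf("need at least 2 windows per half for cross-validation")
  half <- N %/% 2L
  y <- matrix(as.numeric(response)[seq_len(design$T_used)], nrow = design$t0)
  maps <- design_obs_maps(design, dict)
  subdesign <- function(idx) {
    d2 <- design
    d2$S <- design$S[idx]
    d2$N <- length(idx)
    d2$T_used <- length(idx) * design$t0
    d2
  }
  halves <- list(seq_len(half), (half + 1L):N)
  score <- vapply(gammas, function(g) {
    mse <- 0
    for (k in 1:2) {
      train <- halves[[k]]; test <- halves[[3 - k]]
      fit <- rls_fit(subdesign(train),
                     as.numeric(y[, train]), dict, lambda, g, penalty)
      xhat <- fit$states[, ncol(fit$states)]
      for (n in test)
        mse <- mse + mean((y[, n] - as.numeric(maps[[n]] %*% xhat))^2)
    }
    mse / N
  }, numeric(1))
  ord <- order(score, -gammas)     # ties -> larger gamma
  list(gamma = gammas[ord[1]], cv_mse = stats::setNames(score, gammas))
}
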