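#' Windowed Gaussian-mixture process-noise model
#'
#' The process noise of the state equation is governed by a latent label
#' \eqn{z_i \in \{1,\dots,M\}} drawn i.i.d. with probabilities \eqn{p_{1:M}},
#' one label per window of `W` consecutive state steps: for steps
#' \eqn{n = (i-1)W + 1, \dots, iW} the noise is
#' \eqn{w_n \sim N(\mu_{z_i}, \Sigma_{z_i})}. With `W = 1` this reduces to
#' i.i.d. Gaussian-mixture noise; with `M = 1` it reduces to the usual
#' Gaussian state-space model.
#'
#' @param probs Mixture probabilities (length `M`, summing to 1).
#' @param means `d_x x M` matrix of component means (or a vector for `M = 1`).
#' @param covs List of `M` covariance matrices (`d_x x d_x`), or a vector of
#'   variances per component for scalar states.
#' @param W Window length: number of consecutive state steps sharing a label.
#' @param diagonal_only If TRUE, off-diagonals are projected to exactly zero
#'   (the diagonal-covariance model used for TRF estimation).
#' @return Object of class `gm_noise_model` with elements `M`, `probs`,
#'   `means`, `covs`, `W`, `diagonal_only`.
#' @export
gm_noise_model <- function(probs, means, covs, W = 1L, diagonal_only = FALSE) {
  probs <- as.numeric(probs)
  M <- length(probs)
  if (M < 1L) stop_dyntrf("need at least one mixture component")
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop_dyntrf("mixture probabilities must be a simplex vector")
  probs <- probs / sum(probs)
  means <- as.matrix(means)
  if (ncol(means) != M) {
    if (nrow(means) == M) means <- t(means)
    else stop_dyntrf("means must be d_x x M")
  }
  d <- nrow(means)
  if (!is.list(covs)) covs <- lapply(as.numeric(covs), function(v) matrix(v, 1, 1))
  if (length(covs) != M) stop_dyntrf("need one covariance per component")
  covs <- lapply(covs, function(C) {
    C <- sym_psd(as.matrix(C))
    if (nrow(C) != d) stop_dyntrf("covariance dimension mismatch")
    if (diagonal_only) C <- diag(diag(C), d)
    C
  })
  structure(list(M = M, probs = probs, means = means, covs = covs,
                 W = as.integer(W), diagonal_only = diagonal_only),
            class = "gm_noise_model")
}

#' @export
print.gm_noise_model <- function(x, ...) {
  cat(sprintf("gm_noise_model: M = %d components, d_x = %d, W = %d%s\n",
              x$M, nrow(x$means), x$W,
              if (x$diagonal_only) " (diagonal covariances)" else ""))
  cat("  probs:", paste(sprintf("%.3f", x$probs), collapse = " "), "\n")
  invisible(x)
}

# Number of label windows for a spec/model pair, with divisibility check.
n_label_windows <- function(spec, model) {
  if (spec$N %% model$W != 0L)
    stop_dyntrf("number of state windows N = %d is not divisible by W = %d",
                spec$N, model$W)
  spec$N %/% model$W
}

#' Posterior membership probabilities of the mixture labels given a trajectory
#'
#' Evaluates, for each label window `i`, the posterior probability that
#' component `m` generated the process noise of that window, conditioned on a
#' full state trajectory: by Bayes' rule this is proportional to
#' \eqn{p_m \prod_{j=1}^W N(v_{(i,j)}; \mu_m, \Sigma_m)} with
#' \eqn{v_{(i,j)} = x_{(i,j)} - \alpha x_{(i,j-1)}}. Computed in log space.
#'
#' @param trajectory `d_x x (N+1)` matrix of states including the initial
#'   state in column 1 (so column `n+1` is \eqn{x_n}).
#' @param model A [gm_noise_model()].
#' @param spec The [state_space_spec()] (provides `alpha` and `N`).
#' @return `K x M` matrix of membership probabilities; rows sum to 1.
#' @export
membership_probability <- function(trajectory, model, spec) {
  stopifnot(inherits(model, "gm_noise_model"), inherits(spec, "state_space_spec"))
  K <- n_label_windows(spec, model)
  X <- as.matrix(trajectory)
  if (nrow(X) != spec$d_x || ncol(X) != spec$N + 1L)
    stop_dyntrf("trajectory must be d_x x (N+1) including the initial state")
  V <- X[, -1, drop = FALSE] - spec$alpha * X[, -ncol(X), drop = FALSE]
  comp_chol <- lapply(seq_len(model$M), function(m) {
    ch <- tryCatch(chol(model$covs[[m]]), error = function(e) NULL)
    if (is.null(ch))
      stop_dyntrf("covariance of component %d is singular", m)
    ch
  })
  logw <- matrix(0, K, model$M)
  for (m in seq_len(model$M)) {
    ch <- comp_chol[[m]]
    Z <- forwardsolve(t(ch), V - model$means[, m])
    step_ll <- -0.5 * spec$d_x * log(2 * pi) - sum(log(diag(ch))) -
      0.5 * colSums(Z^2)
    win_ll <- colSums(matrix(step_ll, nrow = model$W))
    logw[, m] <- log(model$probs[m]) + win_ll
  }
  out <- exp(logw - apply(logw, 1, logsumexp))
  out / rowSums(out)
}

# Empty e-step moments container; filled by the three E-step backends.
empty_moments <- function(K, M, d) {
  list(
    e0 = matrix(0, K, M),
    e1 = array(0, c(K, M, d)),
    e2 = vector("list", K * M),       # [(i-1)*M + m]
    x_prev = array(0, c(K, M, d)),    # E[eps * sum_j x_{(i,j-1)}]
    xx_prev = vector("list", K * M),  # E[eps * sum_j x_{(i,j-1)} x_{(i,j-1)}']
    x_xprev = vector("list", K * M),  # E[eps * sum_j x_{(i,j)} x_{(i,j-1)}']
    approx_loglik = NA_real_,
    K = K, M = M, d = d)
}

mom_idx <- function(mom, i, m) (i - 1L) * mom$M + m

# Attach the scalar g1/g2 fields of the moment set for a given model
# (the alpha-update cross terms weighted by the model's inverse covariances).
moments_g <- function(mom, model) {
  g1 <- matrix(0, mom$K, mom$M); g2 <- matrix(0, mom$K, mom$M)
  for (m in seq_len(mom$M)) {
    Si <- chol2inv(chol(model$covs[[m]]))
    mu <- model$means[, m]
    for (i in seq_len(mom$K)) {
      k <- mom_idx(mom, i, m)
      g1[i, m] <- sum(Si * mom$xx_prev[[k]])
      g2[i, m] <- sum(Si * t(mom$x_xprev[[k]])) -
        sum(mu * as.numeric(Si %*% mom$x_prev[i, m, ]))
    }
  }
  list(g1 = g1, g2 = g2)
}

#' Exact posterior over label sequences by enumeration (test oracle)
#'
#' Enumerates all \eqn{M^K} label sequences, runs the conditionally-Gaussian
#' Kalman smoother for each, and weights each sequence by its prior times its
#' marginal likelihood. Exact by construction; guarded to small instances.
#' Serves as the independent oracle for the closed-form and Monte Carlo
#' E-step approximations, and as an exact E-step backend for tiny problems.
#'
#' @param spec A [state_space_spec()].
#' @param model A [gm_noise_model()].
#' @param observations As in [kalman_filter()].
#' @return List with `log_posterior` (length `M^K`), `sequences`
#'   (`M^K x K` label matrix), `loglik` (exact data log-likelihood),
#'   `moments` (exact E-step moment set), and `smoothing` (exact per-step
#'   posterior means `d x N`, covariances, and per-step mean/second-moment
#'   summaries used by the observation-noise update).
#' @export
enumerate_label_sequences <- function(spec, model, observations) {
  stopifnot(inherits(spec, "state_space_spec"), inherits(model, "gm_noise_model"))
  K <- n_label_windows(spec, model)
  M <- model$M; d <- spec$d_x; W <- model$W; N <- spec$N
  if (M^K > 1e4)
    stop_dyntrf("M^K = %g label sequences exceed the enumeration guard (1e4); use a smaller instance",
                M^K)
  obs <- as_obs_matrix(spec, observations)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(M)), K)))[, , drop = FALSE]
  colnames(seqs) <- NULL
  nseq <- nrow(seqs)
  logw <- numeric(nseq)
  runs <- vector("list", nseq)
  for (s in seq_len(nseq)) {
    z <- seqs[s, ]
    lab <- rep(z, each = W)
    kf <- kf_run(spec, obs, model$means[, lab, drop = FALSE], model$covs[lab])
    r <- rts_run(kf)
    logw[s] <- sum(log(model$probs[z])) + kf$loglik
    runs[[s]] <- r
  }
  loglik <- logsumexp(logw)
  logpost <- logw - loglik
  post <- exp(logpost)

  mom <- empty_moments(K, M, d)
  mom$approx_loglik <- loglik
  sm_mean <- matrix(0, d, N)
  sm_m2 <- vector("list", N)          # E[x_n x_n' | Y]
  for (n in seq_len(N)) sm_m2[[n]] <- matrix(0, d, d)
  for (s in seq_len(nseq)) {
    w <- post[s]
    if (w == 0) next
    r <- runs[[s]]
    m <- cbind(r$x0_mean, r$means)
    covs <- c(list(r$x0_cov), r$covs)
    for (n in seq_len(N)) {
      sm_mean[, n] <- sm_mean[, n] + w * m[, n + 1]
      sm_m2[[n]] <- sm_m2[[n]] + w * (covs[[n + 1]] + tcrossprod(m[, n + 1]))
    }
    for (i in seq_len(K)) {
      cm <- seqs[s, i]
      k <- mom_idx(mom, i, cm)
      if (is.null(mom$e2[[k]])) {
        mom$e2[[k]] <- matrix(0, d, d)
        mom$xx_prev[[k]] <- matrix(0, d, d)
        mom$x_xprev[[k]] <- matrix(0, d, d)
      }
      for (j in seq_len(W)) {
        n <- (i - 1L) * W + j
        mn <- m[, n + 1]; mp <- m[, n]
        Pn <- covs[[n + 1]]; Pp <- covs[[n]]
        Cnp <- r$lag_one[[n]]                      # Cov(x_n, x_{n-1} | Y, z)
        ev <- mn - spec$alpha * mp
        Cv <- Pn - spec$alpha * Cnp - spec$alpha * t(Cnp) + spec$alpha^2 * Pp
        mom$e1[i, cm, ] <- mom$e1[i, cm, ] + w * ev
        mom$e2[[k]] <- mom$e2[[k]] + w * (Cv + tcrossprod(ev))
        mom$x_prev[i, cm, ] <- mom$x_prev[i, cm, ] + w * mp
        mom$xx_prev[[k]] <- mom$xx_prev[[k]] + w * (Pp + tcrossprod(mp))
        mom$x_xprev[[k]] <- mom$x_xprev[[k]] + w * (Cnp + tcrossprod(mn, mp))
      }
      mom$e0[i, cm] <- mom$e0[i, cm] + w
    }
  }
  zd <- matrix(0, d, d)
  for (k in seq_along(mom$e2))
    if (is.null(mom$e2[[k]])) {
      mom$e2[[k]] <- zd; mom$xx_prev[[k]] <- zd; mom$x_xprev[[k]] <- zd
    }
  smoothing <- list(means = sm_mean, second_moments = sm_m2, loglik = loglik)
  list(log_posterior = logpost, sequences = seqs, loglik = loglik,
       moments = mom, smoothing = smoothing)
}
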