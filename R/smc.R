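#' Particle smoother for the windowed GM process-noise model (Approach 1)
#'
#' Bootstrap sequential Monte Carlo over per-label-window state blocks: for
#' each window a label is sampled from the mixture prior per particle, the `W`
#' state steps are propagated through the transition with noise drawn from the
#' selected component, and the particle is weighted by the Gaussian
#' observation likelihood of the window's samples. Systematic resampling
#' triggers when the effective sample size drops below `U/2`. A backward
#' reweighting pass over the per-window blocks (dimension `(W+1) d_x`) yields
#' marginal smoothing weights per window. Deterministic given `seed`.
#'
#' @inheritParams two_filter_gm_smoother
#' @param U Particle count (>= 2).
#' @param seed RNG seed.
#' @return Object of class `particle_system`: per-window particle `blocks`
#'   (`U x (W+1) d_x`, columns = \eqn{x_{(i,0)}, \ldots, x_{(i,W)}}),
#'   `labels` (`U x K`), filtered log-weights `filt_logw`, smoothed
#'   log-weights `smooth_logw`, `loglik` (SMC likelihood estimate), `ess`,
#'   and `seed`.
#' @export
particle_smoother <- function(spec, model, observations, U = 2000L, seed = 1L) {
  stopifnot(inherits(spec, "state_space_spec"), inherits(model, "gm_noise_model"))
  if (U < 2L) stop_dyntrf("U must be >= 2")
  K <- n_label_windows(spec, model)
  d <- spec$d_x; W <- model$W; t0 <- spec$t0
  obs <- as_obs_matrix(spec, observations)
  chols <- lapply(model$covs, function(C) chol(sym_psd(C)))
  with_seed(seed, {
    blocks <- vector("list", K)
    labels <- matrix(0L, U, K)
    filt_logw <- matrix(0, U, K)
    ess <- numeric(K)
    resampled <- logical(K)
    loglik <- 0
    # initial states from the prior
    x_last <- matrix(rep(spec$x0_mean, each = U), U, d) +
      matrix(stats::rnorm(U * d), U, d) %*% chol(spec$x0_cov)
    logw <- rep(-log(U), U)
    for (i in seq_len(K)) {
      z <- sample.int(model$M, U, replace = TRUE, prob = model$probs)
      blk <- matrix(0, U, (W + 1L) * d)
      blk[, 1:d] <- x_last
      lw_inc <- numeric(U)
      xcur <- x_last
      for (j in seq_len(W)) {
        n <- (i - 1L) * W + j
        noise <- matrix(stats::rnorm(U * d), U, d)
        xnew <- matrix(0, U, d)
        # per-particle component mean and covariance
        for (m in seq_len(model$M)) {
          sel <- which(z == m)
          if (!length(sel)) next
          xnew[sel, ] <- spec$alpha * xcur[sel, , drop = FALSE] +
            matrix(rep(model$means[, m], each = length(sel)), length(sel), d) +
            noise[sel, , drop = FALSE] %*% chols[[m]]
        }
        pred <- xnew %*% t(spec$obs_maps[[n]])      # U x t0
        r <- sweep(pred, 2, obs[, n], function(a, b) b - a)
        lw_inc <- lw_inc - 0.5 * rowSums(r^2) / spec$sigma2 -
          0.5 * t0 * log(2 * pi * spec$sigma2)
        blk[, (j * d + 1L):((j + 1L) * d)] <- xnew
        xcur <- xnew
      }
      lw <- logw + lw_inc
      Z <- logsumexp(lw)
      if (!is.finite(Z))
        stop_dyntrf("all particle weights underflowed in label window %d", i)
      loglik <- loglik + Z
      lw <- lw - Z
      blocks[[i]] <- blk
      labels[, i] <- z
      filt_logw[, i] <- lw
      w <- exp(lw)
      ess[i] <- 1 / sum(w^2)
      if (ess[i] < U / 2 && i < K) {
        idx <- systematic_resample(w)
        x_last <- blk[idx, (W * d + 1L):((W + 1L) * d), drop = FALSE]
        logw <- rep(-log(U), U)
        resampled[i] <- TRUE
      } else {
        x_last <- blk[, (W * d + 1L):((W + 1L) * d), drop = FALSE]
        logw <- lw
      }
    }
    # backward reweighting over blocks; only the first within-block
    # transition couples adjacent blocks, so the pairwise kernel is the
    # d-dimensional transition density of that step.
    smooth_logw <- matrix(0, U, K)
    smooth_logw[, K] <- filt_logw[, K]
    if (K > 1) {
      for (i in seq(K - 1L, 1L)) {
        xW <- blocks[[i]][, (W * d + 1L):((W + 1L) * d), drop = FALSE]  # U x d
        x1 <- blocks[[i + 1L]][, (d + 1L):(2L * d), drop = FALSE]
        z_next <- labels[, i + 1L]
        s_next <- exp(smooth_logw[, i + 1L])
        lw_i <- filt_logw[, i]
        w_i <- exp(lw_i - max(lw_i))
        # accumulate F[u, v] * s_next[v] / (w_i' F[, v]) over v in chunks,
        # with F[u, v] = N(x1[v]; alpha xW[u] + mu_{z_v}, Sigma_{z_v});
        # density-space arithmetic (underflowing terms are negligible)
        acc <- numeric(U)
        chunk <- max(1L, floor(2e6 / U))
        vs <- seq_len(U)
        axW <- spec$alpha * xW
        for (start in seq(1L, U, by = chunk)) {
          vv <- vs[start:min(start + chunk - 1L, U)]
          nv <- length(vv)
          if (d == 1L) {
            mu_v <- model$means[1, z_next[vv]]
            s2_v <- vapply(z_next[vv], function(m) model$covs[[m]][1, 1],
                           numeric(1))
            Dm <- matrix(x1[vv, 1] - mu_v, U, nv, byrow = TRUE) - axW[, 1]
            Fm <- exp(Dm * Dm * rep(-0.5 / s2_v, each = U)) *
              rep(1 / sqrt(2 * pi * s2_v), each = U)
          } else {
            Fm <- matrix(0, U, nv)
            for (m in seq_len(model$M)) {
              selv <- which(z_next[vv] == m)
              if (!length(selv)) next
              ch <- chols[[m]]
              cdet <- exp(-sum(log(diag(ch))) - 0.5 * d * log(2 * pi))
              mu <- model$means[, m]
              Binv <- backsolve(ch, diag(d))
              for (kk in selv) {
                v <- vv[kk]
                diff <- matrix(x1[v, ] - mu, U, d, byrow = TRUE) - axW
                zq <- diff %*% Binv
                Fm[, kk] <- cdet * exp(-0.5 * rowSums(zq * zq))
              }
            }
          }
          denom <- as.numeric(crossprod(Fm, w_i))
          sv <- s_next[vv]
          pos <- denom > 0 & sv > 0
          if (any(pos))
            acc <- acc + as.numeric(Fm[, pos, drop = FALSE] %*%
                                      (sv[pos] / denom[pos]))
        }
        # renormalization constant of w_i cancels between the two sums
        smooth_logw[, i] <- lw_i + log(pmax(acc, 1e-300))
        smooth_logw[, i] <- smooth_logw[, i] - logsumexp(smooth_logw[, i])
      }
    }
    structure(list(U = U, K = K, W = W, d = d, blocks = blocks,
                   labels = labels, filt_logw = filt_logw,
                   smooth_logw = smooth_logw, loglik = loglik, ess = ess,
                   resampled = resampled, seed = seed, spec = spec),
              class = "particle_system")
  })
}

# Systematic (low-variance) resampling of normalized weights.
systematic_resample <- function(w) {
  U <- length(w)
  u0 <- stats::runif(1) / U
  cum <- cumsum(w)
  findInterval(u0 + (seq_len(U) - 1L) / U, cum) + 1L
}

# Per-step smoothed means and second moments from a particle system
# (used by the observation-noise update).
smoothed_moments <- function(ps) {
  d <- ps$d; W <- ps$W; K <- ps$K
  N <- K * W
  means <- matrix(0, d, N)
  m2 <- vector("list", N)
  for (i in seq_len(K)) {
    w <- exp(ps$smooth_logw[, i])
    blk <- ps$blocks[[i]]
    for (j in seq_len(W)) {
      n <- (i - 1L) * W + j
      X <- blk[, (j * d + 1L):((j + 1L) * d), drop = FALSE]
      means[, n] <- as.numeric(crossprod(X, w))
      m2[[n]] <- crossprod(X * w, X)
    }
  }
  list(means = means, second_moments = m2)
}

#' Monte Carlo E-step from smoothed particles
#'
#' Evaluates the membership probabilities \eqn{\hat\epsilon_{i,m}} on every
#' smoothed block sample and averages the weighted moment expressions of the
#' M-step. Rows of `e0` sum to 1 by construction. Monte Carlo standard-error
#' estimates for `e0` are attached as attribute `se_e0`.
#'
#' @param smoothed A `particle_system` from [particle_smoother()].
#' @param model The [gm_noise_model()].
#' @param spec The [state_space_spec()].
#' @return An E-step moment set (same structure as [closed_form_e_step()]).
#' @export
mc_e_step <- function(smoothed, model, spec) {
  stopifnot(inherits(smoothed, "particle_system"))
  ps <- smoothed
  d <- ps$d; W <- ps$W; K <- ps$K; M <- model$M
  mom <- empty_moments(K, M, d)
  mom$approx_loglik <- ps$loglik
  se_e0 <- matrix(0, K, M)
  se_e1 <- array(0, c(K, M, d))
  zd <- matrix(0, d, d)
  for (k in seq_len(K * M)) {
    mom$e2[[k]] <- zd; mom$xx_prev[[k]] <- zd; mom$x_xprev[[k]] <- zd
  }
  chols <- lapply(model$covs, function(C) chol(sym_psd(C)))
  for (i in seq_len(K)) {
    w <- exp(ps$smooth_logw[, i])
    blk <- ps$blocks[[i]]
    U <- ps$U
    # per-particle membership probabilities from the block's residuals
    logeps <- matrix(0, U, M)
    Vs <- vector("list", W)
    for (j in seq_len(W)) {
      Xj <- blk[, (j * d + 1L):((j + 1L) * d), drop = FALSE]
      Xp <- blk[, ((j - 1L) * d + 1L):(j * d), drop = FALSE]
      Vs[[j]] <- Xj - spec$alpha * Xp
    }
    for (m in seq_len(M)) {
      ch <- chols[[m]]
      ld <- sum(log(diag(ch)))
      acc <- rep(log(model$probs[m]), U)
      for (j in seq_len(W)) {
        diff <- sweep(Vs[[j]], 2, model$means[, m])
        zq <- diff %*% backsolve(ch, diag(d))
        acc <- acc - 0.5 * d * log(2 * pi) - ld - 0.5 * rowSums(zq^2)
      }
      logeps[, m] <- acc
    }
    norm <- apply(logeps, 1, logsumexp)
    eps <- exp(logeps - norm)
    sumV <- Reduce(`+`, Vs)
    for (m in seq_len(M)) {
      we <- w * eps[, m]
      k <- mom_idx(mom, i, m)
      mom$e0[i, m] <- sum(we)
      se_e0[i, m] <- sqrt(sum(w^2 * (eps[, m] - sum(we))^2))
      mom$e1[i, m, ] <- as.numeric(crossprod(sumV, we))
      h1 <- sumV * eps[, m]
      se_e1[i, m, ] <- sqrt(colSums(w^2 * sweep(h1, 2, mom$e1[i, m, ])^2))
      for (j in seq_len(W)) {
        Vj <- Vs[[j]]
        Xp <- blk[, ((j - 1L) * d + 1L):(j * d), drop = FALSE]
        Xj <- blk[, (j * d + 1L):((j + 1L) * d), drop = FALSE]
        mom$e2[[k]] <- mom$e2[[k]] + crossprod(Vj * we, Vj)
        mom$x_prev[i, m, ] <- mom$x_prev[i, m, ] + as.numeric(crossprod(Xp, we))
        mom$xx_prev[[k]] <- mom$xx_prev[[k]] + crossprod(Xp * we, Xp)
        mom$x_xprev[[k]] <- mom$x_xprev[[k]] + crossprod(Xj * we, Xp)
      }
    }
    # enforce exact row normalization (weights already sum to 1)
    s <- sum(mom$e0[i, ])
    if (s > 0) mom$e0[i, ] <- mom$e0[i, ] / s
  }
  attr(mom, "se_e0") <- se_e0
  attr(mom, "se_e1") <- se_e1
  mom
}
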