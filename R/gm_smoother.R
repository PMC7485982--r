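#' Gaussian-mixture belief
#'
#' A weighted collection of Gaussian components, optionally capped at a
#' maximum component count (the forward, backward, and smoothing caps of the
#' Gaussian-sum smoother).
#'
#' @param weights Component weights (normalized to the simplex).
#' @param means `d x C` matrix of component means.
#' @param covs List of `C` covariance matrices.
#' @param cap Maximum admissible component count (positive integer or `Inf`).
#' @return Object of class `gm_belief`.
#' @export
gm_belief <- function(weights, means, covs, cap = Inf) {
  weights <- as.numeric(weights)
  if (any(weights < -1e-12)) stop_dyntrf("negative component weight")
  s <- sum(weights)
  if (s <= 0) stop_dyntrf("all component weights vanish")
  weights <- weights / s
  means <- as.matrix(means)
  if (length(weights) > cap)
    stop_dyntrf("component count %d exceeds cap %g", length(weights), cap)
  structure(list(weights = weights, means = means, covs = covs, cap = cap),
            class = "gm_belief")
}

#' Collapse a Gaussian-mixture belief to its overall mean and covariance
#' @param b A [gm_belief()].
#' @return A [gaussian_belief()] with the mixture's first two moments.
#' @export
collapse_belief <- function(b) {
  w <- b$weights
  mean <- as.numeric(b$means %*% w)
  d <- nrow(b$means)
  cov <- matrix(0, d, d)
  for (c in seq_along(w))
    cov <- cov + w[c] * (b$covs[[c]] + tcrossprod(b$means[, c] - mean))
  gaussian_belief(mean, cov)
}

# Reduce a weighted Gaussian mixture (log-weights) to at most `cap`
# components: keep the highest-weight components and replace the remainder by
# its moment-matched Gaussian, conserving the first two moments of the
# discarded mass.
reduce_gaussians <- function(logw, means, covs, cap) {
  C <- length(logw)
  if (!is.finite(cap) || C <= cap)
    return(list(logw = logw, means = means, covs = covs))
  ord <- order(logw, decreasing = TRUE)
  keep <- ord[seq_len(cap - 1L)]
  rest <- ord[cap:C]
  lw_rest <- logw[rest]
  lw_tot <- logsumexp(lw_rest)
  if (lw_tot < -745) {  # negligible mass: drop
    return(list(logw = logw[keep], means = means[, keep, drop = FALSE],
                covs = covs[keep]))
  }
  wr <- exp(lw_rest - lw_tot)
  mu <- as.numeric(means[, rest, drop = FALSE] %*% wr)
  d <- nrow(means)
  P <- matrix(0, d, d)
  for (k in seq_along(rest))
    P <- P + wr[k] * (covs[[rest[k]]] + tcrossprod(means[, rest[k]] - mu))
  list(logw = c(logw[keep], lw_tot),
       means = cbind(means[, keep, drop = FALSE], mu),
       covs = c(covs[keep], list(sym_psd(P))))
}

# Precompute the per-label block transition quantities for blocks of
# W state steps. The extended block state is
# xi_i = (x_{(i,0)}, x_{(i,1)}, ..., x_{(i,W)}), dimension (W+1) d, whose
# first element is the previous block's last state; labels are i.i.d. across
# blocks, so the model is a switching linear-Gaussian SSM at block level.
block_model <- function(spec, model) {
  d <- spec$d_x; W <- model$W; a <- spec$alpha
  D <- (W + 1L) * d
  idx <- lapply(0:W, function(j) (j * d + 1L):((j + 1L) * d))
  Ffull <- matrix(0, D, d)
  for (j in 0:W) Ffull[idx[[j + 1]], ] <- diag(a^j, d)
  per_m <- lapply(seq_len(model$M), function(m) {
    mu <- model$means[, m]; Sg <- model$covs[[m]]
    b <- rep(0, D)
    V <- matrix(0, D, D)
    for (j in 1:W) {
      b[idx[[j + 1]]] <- mu * sum(a^(0:(j - 1)))
      for (jp in 1:W) {
        kmax <- min(j, jp)
        scale <- sum(a^((j - (1:kmax)) + (jp - (1:kmax))))
        V[idx[[j + 1]], idx[[jp + 1]]] <- scale * Sg
      }
    }
    sub <- (d + 1L):D
    Vt <- sym_psd(V[sub, sub, drop = FALSE])      # over (x_{(i,1..W)})
    Vt_chol <- chol(Vt)
    list(b = b, V = V, bt = b[sub], Vt = Vt,
         Vt_inv = chol2inv(Vt_chol),
         Vt_logdet = 2 * sum(log(diag(Vt_chol))))
  })
  list(d = d, W = W, D = D, idx = idx, Ffull = Ffull,
       Ft = Ffull[(d + 1L):D, , drop = FALSE], per_m = per_m)
}

# Block observation matrix and stacked observation vector for block i.
block_obs <- function(spec, bm, i) {
  W <- bm$W; d <- bm$d; t0 <- spec$t0
  H <- matrix(0, W * t0, bm$D)
  for (j in 1:W) {
    n <- (i - 1L) * W + j
    rows <- ((j - 1L) * t0 + 1L):(j * t0)
    H[rows, bm$idx[[j + 1]]] <- spec$obs_maps[[n]]
  }
  H
}

#' Two-filter Gaussian-sum smoother for the windowed GM process-noise model
#'
#' Closed-form approximation of the joint smoothing distribution: a forward
#' Gaussian-sum filter over label-window blocks (each prediction branches over
#' the `M` mixture components, then reduces to at most `gamma_f` components),
#' a backward information-form Gaussian-sum message (cap `gamma_b`), and a
#' canonical-form combination producing, per label window, the posterior label
#' probabilities and per-label Gaussian-mixture beliefs over the whole block
#' \eqn{(x_{(i,0)}, \ldots, x_{(i,W)})} — which carry the within-window
#' one-step cross-covariances needed by the EM sufficient statistics. The
#' approximate data log-likelihood is the accumulated forward normalization
#' constant. With unbounded caps no reduction occurs and the returned
#' posterior and log-likelihood are exact (they match
#' [enumerate_label_sequences()]).
#'
#' @param spec A [state_space_spec()].
#' @param model A [gm_noise_model()]; `N` must be divisible by its `W`.
#' @param observations As in [kalman_filter()].
#' @param caps Numeric vector `(gamma_f, gamma_b, gamma_s)` of component caps
#'   for the forward, backward, and smoothing mixtures; `Inf` disables
#'   reduction.
#' @return Object of class `gm_smoothed`: `steps` (per-state-step smoothing
#'   [gm_belief()]s, reduced to `gamma_s`), `means`/`second_moments`
#'   (posterior-collapsed per-step moments), `cross_moments` (collapsed
#'   \eqn{E[x_n x_{n-1}' | Y]} per step), `e0` (`K x M` posterior label
#'   probabilities), `moments` (the E-step moment set), and `approx_loglik`.
#' @export
two_filter_gm_smoother <- function(spec, model, observations,
                                   caps = c(Inf, Inf, Inf)) {
  stopifnot(inherits(spec, "state_space_spec"), inherits(model, "gm_noise_model"))
  caps <- as.numeric(caps)
  if (length(caps) == 1L) caps <- rep(caps, 3L)
  if (any(caps < 1)) stop_dyntrf("all reduction caps must be >= 1")
  gamma_f <- caps[1]; gamma_b <- caps[2]; gamma_s <- caps[3]
  K <- n_label_windows(spec, model)
  M <- model$M; d <- spec$d_x; W <- model$W; N <- spec$N; t0 <- spec$t0
  obs <- as_obs_matrix(spec, observations)
  if (d == 1L && W == 1L && t0 == 1L)
    return(two_filter_gm_scalar(spec, model, obs,
                                c(gamma_f, gamma_b, gamma_s)))
  bm <- block_model(spec, model)
  D <- bm$D
  Ylist <- lapply(seq_len(K), function(i)
    as.numeric(obs[, ((i - 1L) * W + 1L):(i * W), drop = FALSE]))
  Hlist <- lapply(seq_len(K), function(i) block_obs(spec, bm, i))

  ## ---- forward Gaussian-sum filter over blocks ----
  tagged <- vector("list", K)   # per block: tagged, updated components
  loglik <- 0
  prev_logw <- 0
  prev_means <- matrix(spec$x0_mean, d, 1)
  prev_covs <- list(spec$x0_cov)
  for (i in seq_len(K)) {
    H <- Hlist[[i]]; Y <- Ylist[[i]]
    n_prev <- length(prev_logw)
    lw <- numeric(0); mns <- NULL; cvs <- list(); tags <- integer(0)
    for (c in seq_len(n_prev)) {
      for (m in seq_len(M)) {
        pm <- bm$per_m[[m]]
        mean_pred <- as.numeric(bm$Ffull %*% prev_means[, c]) + pm$b
        cov_pred <- bm$Ffull %*% prev_covs[[c]] %*% t(bm$Ffull) + pm$V
        cov_pred <- (cov_pred + t(cov_pred)) / 2
        up <- kf_update(mean_pred, cov_pred, H, Y, spec$sigma2)
        lw <- c(lw, prev_logw[c] + log(model$probs[m]) + up$loglik)
        mns <- cbind(mns, up$mean)
        cvs <- c(cvs, list(up$cov))
        tags <- c(tags, m)
      }
    }
    if (all(!is.finite(lw)))
      stop_dyntrf("all forward component weights underflowed in label window %d", i)
    Z <- logsumexp(lw)
    loglik <- loglik + Z
    lw <- lw - Z
    tagged[[i]] <- list(logw = lw, means = mns, covs = cvs, tags = tags)
    # propagate the marginal of the last block element, reduced to gamma_f
    red <- reduce_gaussians(lw, mns, cvs, gamma_f)
    last <- bm$idx[[W + 1]]
    prev_logw <- red$logw - logsumexp(red$logw)
    prev_means <- red$means[last, , drop = FALSE]
    prev_covs <- lapply(red$covs, function(P) P[last, last, drop = FALSE])
  }

  ## ---- backward information-form messages lambda_i(x_{iW}) ----
  ## lambda_i(x) = p(Y_{i+1:K} | x_{iW} = x), a mixture of canonical forms
  ## exp(g + h'x - x' L x / 2). Terminal message: uninformative.
  lambda <- vector("list", K)
  lambda[[K]] <- list(list(L = matrix(0, d, d), h = rep(0, d), g = 0))
  if (K > 1) {
    Wd <- W * d
    last_sub <- (Wd - d + 1L):Wd      # x_{(i,W)} within (x_{(i,1..W)})
    for (i in seq(K - 1L, 1L)) {
      H <- Hlist[[i + 1L]][, (d + 1L):D, drop = FALSE]  # maps (x_{1..W})
      Y <- Ylist[[i + 1L]]
      HtH <- crossprod(H) / spec$sigma2
      HtY <- as.numeric(crossprod(H, Y)) / spec$sigma2
      g_obs <- -0.5 * sum(Y^2) / spec$sigma2 -
        0.5 * (W * t0) * log(2 * pi * spec$sigma2)
      comps <- list()
      for (m in seq_len(M)) {
        pm <- bm$per_m[[m]]
        Vinv <- pm$Vt_inv
        VinvF <- Vinv %*% bm$Ft
        Vinvb <- as.numeric(Vinv %*% pm$bt)
        gN <- -0.5 * sum(pm$bt * Vinvb) -
          0.5 * (Wd * log(2 * pi) + pm$Vt_logdet) + log(model$probs[m]) + g_obs
        for (cc in lambda[[i + 1L]]) {
          J <- HtH
          J[last_sub, last_sub] <- J[last_sub, last_sub] + cc$L
          hX <- HtY
          hX[last_sub] <- hX[last_sub] + cc$h
          KXX <- Vinv + J
          Kch <- chol_safe(KXX)
          eta_X <- Vinvb + hX
          sol_eta <- backsolve(Kch, forwardsolve(t(Kch), eta_X))
          sol_VF <- backsolve(Kch, forwardsolve(t(Kch), VinvF))
          L_out <- crossprod(bm$Ft, VinvF) - crossprod(VinvF, sol_VF)
          L_out <- (L_out + t(L_out)) / 2
          h_out <- -as.numeric(crossprod(bm$Ft, Vinvb)) +
            as.numeric(crossprod(VinvF, sol_eta))
          g_out <- gN + cc$g + 0.5 * sum(eta_X * sol_eta) +
            0.5 * Wd * log(2 * pi) - sum(log(diag(Kch)))
          comps <- c(comps, list(list(L = L_out, h = h_out, g = g_out)))
        }
      }
      lambda[[i]] <- reduce_canonical(comps, gamma_b, d)
    }
  }

  ## ---- combination: block posteriors and moments ----
  mom <- empty_moments(K, M, d)
  mom$approx_loglik <- loglik
  e0 <- matrix(0, K, M)
  sm_mean <- matrix(0, d, N)
  sm_m2 <- lapply(seq_len(N), function(n) matrix(0, d, d))
  cross <- lapply(seq_len(N), function(n) matrix(0, d, d))
  steps <- vector("list", N)
  step_comp <- lapply(seq_len(N), function(n)
    list(logw = numeric(0), means = NULL, covs = list()))
  last <- bm$idx[[W + 1]]
  zd <- matrix(0, d, d)
  for (k in seq_len(K * M)) {
    mom$e2[[k]] <- zd; mom$xx_prev[[k]] <- zd; mom$x_xprev[[k]] <- zd
  }
  for (i in seq_len(K)) {
    tg <- tagged[[i]]
    lw_all <- numeric(0); post <- list(); tag_all <- integer(0)
    for (c in seq_along(tg$logw)) {
      mu_f <- tg$means[, c]; P_f <- tg$covs[[c]]
      Pch <- chol_safe(P_f)
      Pinv <- chol2inv(Pch)
      base_eta <- as.numeric(Pinv %*% mu_f)
      g_f <- -0.5 * sum(mu_f * base_eta)
      ld_P <- 2 * sum(log(diag(Pch)))
      for (cc in lambda[[i]]) {
        Kp <- Pinv
        Kp[last, last] <- Kp[last, last] + cc$L
        eta <- base_eta
        eta[last] <- eta[last] + cc$h
        Kch <- chol_safe(Kp)
        mean_p <- backsolve(Kch, forwardsolve(t(Kch), eta))
        cov_p <- chol2inv(Kch)
        # overlap integral of N(xi; mu_f, P_f) with the canonical likelihood
        ell <- g_f - 0.5 * ld_P + 0.5 * sum(eta * mean_p) -
          sum(log(diag(Kch)))
        lw_all <- c(lw_all, tg$logw[c] + cc$g + ell)
        post <- c(post, list(list(mean = mean_p, cov = cov_p)))
        tag_all <- c(tag_all, tg$tags[c])
      }
    }
    if (all(!is.finite(lw_all)))
      stop_dyntrf("all smoothing component weights underflowed in label window %d", i)
    w_all <- exp(lw_all - logsumexp(lw_all))
    for (p in seq_along(post)) {
      w <- w_all[p]
      if (w < 1e-300) next
      m_tag <- tag_all[p]
      k <- mom_idx(mom, i, m_tag)
      mu <- post[[p]]$mean; P <- post[[p]]$cov
      e0[i, m_tag] <- e0[i, m_tag] + w
      for (j in 1:W) {
        n <- (i - 1L) * W + j
        ij <- bm$idx[[j + 1]]; ip <- bm$idx[[j]]
        mj <- mu[ij]; mp <- mu[ip]
        Pjj <- P[ij, ij, drop = FALSE]
        Ppp <- P[ip, ip, drop = FALSE]
        Pjp <- P[ij, ip, drop = FALSE]
        ev <- mj - spec$alpha * mp
        Cv <- Pjj - spec$alpha * Pjp - spec$alpha * t(Pjp) +
          spec$alpha^2 * Ppp
        mom$e1[i, m_tag, ] <- mom$e1[i, m_tag, ] + w * ev
        mom$e2[[k]] <- mom$e2[[k]] + w * (Cv + tcrossprod(ev))
        mom$x_prev[i, m_tag, ] <- mom$x_prev[i, m_tag, ] + w * mp
        mom$xx_prev[[k]] <- mom$xx_prev[[k]] + w * (Ppp + tcrossprod(mp))
        mom$x_xprev[[k]] <- mom$x_xprev[[k]] + w * (Pjp + tcrossprod(mj, mp))
        sm_mean[, n] <- sm_mean[, n] + w * mj
        sm_m2[[n]] <- sm_m2[[n]] + w * (Pjj + tcrossprod(mj))
        cross[[n]] <- cross[[n]] + w * (Pjp + tcrossprod(mj, mp))
        sc <- step_comp[[n]]
        sc$logw <- c(sc$logw, log(w))
        sc$means <- cbind(sc$means, mj)
        sc$covs <- c(sc$covs, list((Pjj + t(Pjj)) / 2))
        step_comp[[n]] <- sc
      }
    }
  }
  mom$e0 <- e0
  for (n in seq_len(N)) {
    sc <- step_comp[[n]]
    red <- reduce_gaussians(sc$logw - logsumexp(sc$logw), sc$means, sc$covs,
                            gamma_s)
    steps[[n]] <- gm_belief(exp(red$logw - logsumexp(red$logw)),
                            red$means, red$covs, cap = gamma_s)
  }
  structure(list(steps = steps, means = sm_mean, second_moments = sm_m2,
                 cross_moments = cross, e0 = e0, moments = mom,
                 approx_loglik = loglik, caps = caps, K = K, model = model),
            class = "gm_smoothed")
}

# Reduce a list of canonical-form components exp(g + h'x - x'Lx/2) to `cap`
# components, ranked by total mass (log-integral when the information matrix
# is positive definite, otherwise by the log-scale g); the surplus mass is
# merged moment-matched when invertible, else dropped.
reduce_canonical <- function(comps, cap, d) {
  C <- length(comps)
  if (!is.finite(cap) || C <= cap) return(comps)
  mass <- vapply(comps, function(cc) {
    ch <- tryCatch(chol(sym_psd(cc$L, 0) + diag(1e-12, d)), error = function(e) NULL)
    if (is.null(ch)) return(cc$g)
    s <- backsolve(ch, forwardsolve(t(ch), cc$h))
    cc$g + 0.5 * sum(cc$h * s) + 0.5 * d * log(2 * pi) - sum(log(diag(ch)))
  }, numeric(1))
  ord <- order(mass, decreasing = TRUE)
  keep <- comps[ord[seq_len(cap - 1L)]]
  rest_idx <- ord[cap:C]
  moments <- list(); lw <- numeric(0)
  for (r in rest_idx) {
    cc <- comps[[r]]
    ch <- tryCatch(chol(sym_psd(cc$L, 0) + diag(1e-12, d)), error = function(e) NULL)
    if (is.null(ch)) next     # negligible / improper surplus component
    P <- chol2inv(ch)
    moments <- c(moments, list(list(mean = as.numeric(P %*% cc$h), cov = P)))
    lw <- c(lw, mass[r])
  }
  if (!length(lw)) return(keep)
  lt <- logsumexp(lw)
  wr <- exp(lw - lt)
  mu <- Reduce(`+`, Map(function(mm, w) w * mm$mean, moments, wr))
  P <- Reduce(`+`, Map(function(mm, w)
    w * (mm$cov + tcrossprod(mm$mean - mu)), moments, wr))
  P <- sym_psd(P)
  Pinv <- chol2inv(chol(P))
  h <- as.numeric(Pinv %*% mu)
  g <- lt - (0.5 * sum(h * mu) + 0.5 * d * log(2 * pi) - 0.5 * logdet_pd(Pinv))
  c(keep, list(list(L = Pinv, h = h, g = g)))
}

#' Closed-form E-step for the GM process-noise EM (Approach 2)
#'
#' Runs [two_filter_gm_smoother()] and extracts the E-step conditional
#' expectations: per label window `i` and component `m`, the posterior label
#' probability `e0`, the first and second moments `e1`/`e2` of the summed
#' within-window process-noise residuals \eqn{v_{(i,j)} = x_{(i,j)} - \alpha
#' x_{(i,j-1)}}, and the cross-moment blocks from which the transition
#' coefficient update is assembled. Exact when the caps are unbounded.
#'
#' @inheritParams two_filter_gm_smoother
#' @return The E-step moment set (fields `e0`, `e1`, `e2`, `x_prev`,
#'   `xx_prev`, `x_xprev`, `approx_loglik`), with the smoother output in
#'   attribute `smoothing`. `rowSums(e0)` is 1 for every window.
#' @export
closed_form_e_step <- function(spec, model, observations, caps = c(Inf, Inf, Inf)) {
  sm <- two_filter_gm_smoother(spec, model, observations, caps)
  mom <- sm$moments
  attr(mom, "smoothing") <- sm
  mom
}
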