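#' Markov-switching autoregressive model on surrogate TRF states
#'
#' Fits a first-order Markov-switching AR(1) model to a directly observed
#' state sequence (the regularized least-squares TRF surrogate,
#' [rls_fit()] with `lambda = 0`): regime `j` has dynamics
#' \eqn{x_n = \alpha_j x_{n-1} + w_{j,n}}, \eqn{w_{j,n} \sim N(\mu_j, Q_j)},
#' regimes following a hidden Markov chain with initial probabilities
#' \eqn{\pi} and transition matrix `P`. Estimated by Baum-Welch EM: a
#' forward-backward pass over regimes with Gaussian emission of the
#' innovations, followed by weighted regime-wise updates of
#' \eqn{(\alpha_j, \mu_j, Q_j)} and expected-count updates of \eqn{\pi, P}.
#' Covariances are kept diagonal.
#'
#' @param states `d x N` surrogate state sequence.
#' @param J Number of regimes (>= 1).
#' @param config List: `max_iters` (default 100), `tol` (default 1e-8),
#'   `seed` (k-means initialization on innovations), `var_floor`.
#' @return Object of class `msar_model`: `J`, `pi0`, `P`, `alpha` (length
#'   `J`), `mu` (`d x J`), `Q` (list), `omega` (`J x N` filtered regime
#'   probabilities), `gamma` (smoothed regime probabilities), `logliks`.
#' @export
msar_fit <- function(states, J, config = list()) {
  if (J < 1L) stop_dyntrf("J must be >= 1")
  cfg <- modifyList(list(max_iters = 100L, tol = 1e-8, seed = 1L,
                         var_floor = 1e-10), config)
  X <- as.matrix(states)
  d <- nrow(X); N <- ncol(X)
  if (N < J + 1L) stop_dyntrf("too few windows for %d regimes", J)
  # innovations under a unit-AR surrogate, clustered for initialization
  V <- X[, -1, drop = FALSE] - X[, -N, drop = FALSE]
  # variance floor relative to the innovation scale (guards degenerate
  # regimes from hijacking the likelihood)
  cfg$var_floor <- max(cfg$var_floor, 1e-6 * mean(apply(V, 1, stats::var)))
  if (J == 1L) {
    cl <- rep(1L, N - 1L)
  } else {
    km <- with_seed(cfg$seed, stats::kmeans(t(V), centers = J, nstart = 5L))
    cl <- km$cluster
  }
  alpha <- numeric(J); mu <- matrix(0, d, J); Q <- vector("list", J)
  for (j in seq_len(J)) {
    sel <- which(cl == j)
    if (length(sel) < 2L) sel <- seq_len(N - 1L)
    a <- ar1_coef(X, sel)
    alpha[j] <- a
    Vj <- X[, sel + 1L, drop = FALSE] - a * X[, sel, drop = FALSE]
    mu[, j] <- rowMeans(Vj)
    qv <- pmax(apply(Vj, 1, stats::var), cfg$var_floor)
    qv[!is.finite(qv)] <- 1
    Q[[j]] <- diag(qv, d)
  }
  pi0 <- rep(1 / J, J)
  P <- matrix(0.1 / max(J - 1, 1), J, J); diag(P) <- if (J > 1) 0.9 else 1
  P <- P / rowSums(P)
  logliks <- numeric(0)
  Tn <- N - 1L   # transitions n = 2..N
  emissions <- function() {
    B <- matrix(0, J, Tn)
    for (j in seq_len(J)) {
      ch <- chol(Q[[j]])
      ld <- sum(log(diag(ch)))
      Vj <- X[, -1, drop = FALSE] - alpha[j] * X[, -N, drop = FALSE] - mu[, j]
      Zq <- forwardsolve(t(ch), Vj)
      B[j, ] <- -0.5 * d * log(2 * pi) - ld - 0.5 * colSums(Zq^2)
    }
    B
  }
  fb <- NULL
  for (it in seq_len(cfg$max_iters)) {
    B <- emissions()
    fb <- hmm_forward_backward(pi0, P, B)
    logliks <- c(logliks, fb$loglik)
    # M-step
    g <- fb$gamma                       # J x Tn
    xi <- fb$xi                         # J x J expected transition counts
    pi0 <- pmax(g[, 1], 1e-12)
    pi0 <- pi0 / sum(pi0)
    if (J > 1) {
      P <- xi / pmax(rowSums(xi), 1e-300)
      P[rowSums(xi) < 1e-300, ] <- 1 / J
    }
    for (j in seq_len(J)) {
      w <- g[j, ]
      sw <- sum(w)
      if (sw < 1e-12) {
        message(sprintf("MSAR regime %d received no responsibility; parameters frozen", j))
        next
      }
      Xp <- X[, -N, drop = FALSE]; Xn <- X[, -1, drop = FALSE]
      Qi <- chol2inv(chol(Q[[j]]))
      # coordinate updates: alpha_j given mu_j, then mu_j, then Q_j
      num <- sum(w * colSums((Qi %*% Xp) * (Xn - mu[, j])))
      den <- sum(w * colSums((Qi %*% Xp) * Xp))
      if (den > 0) alpha[j] <- num / den
      Vj <- Xn - alpha[j] * Xp
      mu[, j] <- as.numeric(Vj %*% w) / sw
      R <- Vj - mu[, j]
      qv <- pmax(as.numeric((R^2) %*% w) / sw, cfg$var_floor)
      Q[[j]] <- diag(qv, d)
    }
    if (it > 1 &&
        abs(logliks[it] - logliks[it - 1]) / (abs(logliks[it]) + 1e-12) < cfg$tol)
      break
  }
  # filtered regime probabilities omega_{j,n} = P(s_n = j | x_{1:n})
  omega <- hmm_filter(pi0, P, emissions())
  structure(list(J = J, pi0 = pi0, P = P, alpha = alpha, mu = mu, Q = Q,
                 omega = omega, gamma = fb$gamma,
                 logliks = logliks, d = d, N = N),
            class = "msar_model")
}

ar1_coef <- function(X, sel) {
  num <- sum(X[, sel + 1L, drop = FALSE] * X[, sel, drop = FALSE])
  den <- sum(X[, sel, drop = FALSE]^2)
  if (den <= 0) 1 else num / den
}

# Standard scaled HMM forward-backward; emissions B are log-densities
# (J x T). Returns smoothed gamma, expected transition counts xi, loglik.
hmm_forward_backward <- function(pi0, P, B) {
  J <- nrow(B); Tn <- ncol(B)
  la <- matrix(-Inf, J, Tn)
  la[, 1] <- log(pi0) + B[, 1]
  if (Tn > 1) for (t in 2:Tn) {
    for (j in seq_len(J))
      la[j, t] <- logsumexp(la[, t - 1] + log(P[, j])) + B[j, t]
  }
  loglik <- logsumexp(la[, Tn])
  lb <- matrix(0, J, Tn)
  if (Tn > 1) for (t in seq(Tn - 1L, 1L)) {
    for (j in seq_len(J))
      lb[j, t] <- logsumexp(log(P[j, ]) + B[, t + 1] + lb[, t + 1])
  }
  lg <- la + lb - loglik
  gam <- exp(lg)
  cs <- colSums(gam)
  bad <- !is.finite(cs) | cs <= 0
  if (any(bad)) gam[, bad] <- 1 / J
  gam <- sweep(gam, 2, pmax(colSums(gam), 1e-300), `/`)
  xi <- matrix(0, J, J)
  if (Tn > 1) {
    for (t in seq_len(Tn - 1L)) {
      lx <- matrix(la[, t], J, J) + log(P) +
        matrix(B[, t + 1] + lb[, t + 1], J, J, byrow = TRUE) - loglik
      xi <- xi + exp(lx)
    }
  }
  list(gamma = gam, xi = xi, loglik = loglik)
}

hmm_filter <- function(pi0, P, B) {
  J <- nrow(B); Tn <- ncol(B)
  om <- matrix(0, J, Tn)
  lp <- log(pi0) + B[, 1]
  om[, 1] <- exp(lp - logsumexp(lp))
  if (Tn > 1) for (t in 2:Tn) {
    pred <- as.numeric(t(P) %*% om[, t - 1])
    lp <- log(pmax(pred, 1e-300)) + B[, t]
    om[, t] <- exp(lp - logsumexp(lp))
  }
  om
}

#' One-step MSAR state estimates
#'
#' Causal regime-averaged predictions
#' \eqn{\hat x_n^{MSAR} = \sum_j \omega_{j,n} (\mu_j + \alpha_j \hat
#' x_{n-1})} using the filtered regime probabilities, mapped through the
#' dictionary into a [trf_series()].
#'
#' @param model A fitted [msar_fit()].
#' @param states The surrogate state sequence the model was fitted on.
#' @param dict,t0 Dictionary and window length for the output container.
#' @return A [trf_series()] (first window copies the surrogate).
#' @export
msar_estimate <- function(model, states, dict, t0) {
  X <- as.matrix(states)
  d <- nrow(X); N <- ncol(X)
  out <- X
  for (n in 2:N) {
    pred <- matrix(0, d, 1)
    for (j in seq_len(model$J))
      pred <- pred + model$omega[j, n - 1] *
        (model$mu[, j] + model$alpha[j] * X[, n - 1])
    out[, n] <- pred
  }
  trf_series(out, dict, t0, estimator = sprintf("msar(J=%d)", model$J))
}

#' Extract M100 magnitudes from a TRF series
#'
#' Per speaker and window, the M100 magnitude is the absolute value of the
#' minimum TRF element over the lag interval (default [0.1, 0.2] s, endpoints
#' included on the sample grid); the attention-modulated M100 is a negative
#' deflection, so the window minimum locates it. If no negative deflection
#' exists, the magnitude of the smallest (positive) value is returned and
#' flagged in the `degenerate` field. Ties break toward the earliest lag.
#'
#' @param trf A [trf_series()].
#' @param lag_window Closed lag interval in seconds.
#' @return List with `m100_1`, `m100_2` (per-window magnitudes),
#'   `difference` (`m100_1 - m100_2`), `time_s`, and `degenerate` (logical
#'   matrix, windows x speakers, TRUE where no negative deflection existed).
#' @export
extract_m100 <- function(trf, lag_window = c(0.1, 0.2)) {
  sel <- which(trf$lags >= lag_window[1] - 1e-9 &
                 trf$lags <= lag_window[2] + 1e-9)
  if (!length(sel)) stop_dyntrf("lag window [%g, %g] s outside TRF support",
                                lag_window[1], lag_window[2])
  mag <- function(tau) {
    vals <- apply(tau[sel, , drop = FALSE], 2, min)
    abs(vals)
  }
  m1 <- mag(trf$tau1); m2 <- mag(trf$tau2)
  deg <- cbind(apply(trf$tau1[sel, , drop = FALSE], 2, min) > 0,
               apply(trf$tau2[sel, , drop = FALSE], 2, min) > 0)
  list(m100_1 = m1, m100_2 = m2, difference = m1 - m2,
       time_s = trf$time_s, degenerate = deg)
}

#' Decode auditory attention from M100 magnitude differences
#'
#' Decision per window: speaker 1 is decoded as attended iff the M100
#' magnitude difference (speaker 1 minus speaker 2) is strictly positive.
#' An exactly zero difference counts as misclassified (no evidence).
#'
#' @param difference Per-window difference series from [extract_m100()].
#' @param schedule Attended-speaker labels per window (1 or 2).
#' @return List with `decision` (1/2 per window), `correct` (logical),
#'   `misclassification_rate` (percent).
#' @export
decode_attention <- function(difference, schedule) {
  if (length(difference) != length(schedule))
    stop_dyntrf("difference series (%d) and schedule (%d) lengths differ",
                length(difference), length(schedule))
  decision <- ifelse(difference > 0, 1L, 2L)
  correct <- decision == schedule & difference != 0
  list(decision = decision, correct = correct,
       misclassification_rate = 100 * mean(!correct))
}
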