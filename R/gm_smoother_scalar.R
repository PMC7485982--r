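# Vectorized fast path of the two-filter Gaussian-sum smoother for scalar
# states with one state step per label window and one sample per window
# (d_x = 1, W = 1, t0 = 1). Implements exactly the same algorithm as the
# generic block path — forward GM filter over (x_{i-1}, x_i) blocks,
# backward information-form messages, canonical combination — with all
# 2x2/1x1 linear algebra unrolled to elementwise vector arithmetic across
# mixture components. Dispatch happens in two_filter_gm_smoother(); the
# equality of the two paths is enforced by tests.
two_filter_gm_scalar <- function(spec, model, obs, caps) {
  gamma_f <- caps[1]; gamma_b <- caps[2]; gamma_s <- caps[3]
  K <- spec$N; M <- model$M
  a <- spec$alpha; s2 <- spec$sigma2
  amap <- vapply(spec$obs_maps, function(A) A[1, 1], numeric(1))
  y <- as.numeric(obs)
  p_m <- model$probs
  mu_m <- as.numeric(model$means)
  q_m <- vapply(model$covs, function(C) C[1, 1], numeric(1))

  ## ---- forward pass over blocks (x_{i-1}, x_i) ----
  # component state: logw, m1, m2, p11, p12, p22, tag
  tagged <- vector("list", K)
  loglik <- 0
  # "previous" marginal of the last element: start at the x0 prior
  pr_lw <- 0; pr_m <- spec$x0_mean[1]; pr_P <- spec$x0_cov[1, 1]
  for (i in seq_len(K)) {
    nc <- length(pr_lw)
    # branch every parent over every mixture component
    lw <- rep(pr_lw, each = M) + rep(log(p_m), nc)
    tag <- rep.int(seq_len(M), nc)
    m1 <- rep(pr_m, each = M)
    p11 <- rep(pr_P, each = M)
    mu <- mu_m[tag]; q <- q_m[tag]
    m2 <- a * m1 + mu
    p12 <- a * p11
    p22 <- a^2 * p11 + q
    # scalar observation y_i = amap_i * x_i + noise
    ai <- amap[i]
    S <- ai^2 * p22 + s2
    r <- y[i] - ai * m2
    lw <- lw - 0.5 * log(2 * pi * S) - 0.5 * r^2 / S
    k1 <- ai * p12 / S; k2 <- ai * p22 / S
    m1 <- m1 + k1 * r; m2 <- m2 + k2 * r
    p11 <- p11 - k1 * ai * p12
    p12n <- p12 - k1 * ai * p22
    p22 <- p22 - k2 * ai * p22
    p12 <- p12n
    if (all(!is.finite(lw)))
      stop_dyntrf("all forward component weights underflowed in label window %d", i)
    Z <- logsumexp(lw)
    loglik <- loglik + Z
    lw <- lw - Z
    tagged[[i]] <- list(lw = lw, m1 = m1, m2 = m2, p11 = p11, p12 = p12,
                        p22 = p22, tag = tag)
    red <- reduce_scalar_gaussians(lw, m2, p22, gamma_f)
    pr_lw <- red$lw; pr_m <- red$m; pr_P <- red$P
  }

  ## ---- backward information messages on x_i ----
  lam <- vector("list", K)
  lam[[K]] <- list(L = 0, h = 0, g = 0)
  if (K > 1) {
    for (i in seq(K - 1L, 1L)) {
      nxt <- lam[[i + 1L]]
      nl <- length(nxt$L)
      ai <- amap[i + 1L]; yi <- y[i + 1L]
      # expand (lambda component c) x (mixture m)
      L_c <- rep(nxt$L, each = M); h_c <- rep(nxt$h, each = M)
      g_c <- rep(nxt$g, each = M)
      mu <- rep.int(mu_m, nl); q <- rep.int(q_m, nl)
      lp <- rep.int(log(p_m), nl)
      J <- ai^2 / s2 + L_c
      hX <- ai * yi / s2 + h_c
      g0 <- g_c + lp - yi^2 / (2 * s2) - 0.5 * log(2 * pi * s2)
      KXX <- 1 / q + J
      etaX <- mu / q + hX
      L_out <- a^2 / q - (a / q)^2 / KXX
      h_out <- -a * mu / q + (a / q) * etaX / KXX
      g_out <- g0 - mu^2 / (2 * q) - 0.5 * log(2 * pi * q) +
        etaX^2 / (2 * KXX) + 0.5 * log(2 * pi) - 0.5 * log(KXX)
      lam[[i]] <- reduce_scalar_canonical(L_out, h_out, g_out, gamma_b)
    }
  }

  ## ---- combination and moments ----
  mom <- empty_moments(K, M, 1L)
  mom$approx_loglik <- loglik
  e0 <- matrix(0, K, M)
  sm_mean <- matrix(0, 1, K)
  sm_m2 <- vector("list", K)
  cross <- vector("list", K)
  steps <- vector("list", K)
  for (i in seq_len(K)) {
    tg <- tagged[[i]]
    la <- lam[[i]]
    nf <- length(tg$lw); nl <- length(la$L)
    f <- rep(seq_len(nf), each = nl); cidx <- rep.int(seq_len(nl), nf)
    m1 <- tg$m1[f]; m2 <- tg$m2[f]
    p11 <- tg$p11[f]; p12 <- tg$p12[f]; p22 <- tg$p22[f]
    Lc <- la$L[cidx]; hc <- la$h[cidx]; gc <- la$g[cidx]
    det_P <- pmax(p11 * p22 - p12^2, 1e-300)
    i11 <- p22 / det_P; i12 <- -p12 / det_P; i22 <- p11 / det_P
    # posterior precision: P^-1 + diag(0, Lc); eta = P^-1 mu + (0, hc)
    k11 <- i11; k12 <- i12; k22 <- i22 + Lc
    det_K <- pmax(k11 * k22 - k12^2, 1e-300)
    e1v <- i11 * m1 + i12 * m2
    e2v <- i12 * m1 + i22 * m2 + hc
    # posterior moments
    q11 <- k22 / det_K; q12 <- -k12 / det_K; q22 <- k11 / det_K
    pm1 <- q11 * e1v + q12 * e2v
    pm2 <- q12 * e1v + q22 * e2v
    quad_mu <- m1 * (i11 * m1 + i12 * m2) + m2 * (i12 * m1 + i22 * m2)
    quad_eta <- e1v * pm1 + e2v * pm2
    ell <- -0.5 * quad_mu - 0.5 * log(det_P) + 0.5 * quad_eta -
      0.5 * log(det_K)
    lw <- tg$lw[f] + gc + ell
    if (all(!is.finite(lw)))
      stop_dyntrf("all smoothing component weights underflowed in label window %d", i)
    w <- exp(lw - logsumexp(lw))
    tagv <- tg$tag[f]
    ev <- pm2 - a * pm1
    cv <- q22 - 2 * a * q12 + a^2 * q11
    for (m in seq_len(M)) {
      sel <- tagv == m
      ws <- w[sel]
      k <- mom_idx(mom, i, m)
      e0[i, m] <- sum(ws)
      mom$e1[i, m, 1] <- sum(ws * ev[sel])
      mom$e2[[k]] <- matrix(sum(ws * (cv[sel] + ev[sel]^2)), 1, 1)
      mom$x_prev[i, m, 1] <- sum(ws * pm1[sel])
      mom$xx_prev[[k]] <- matrix(sum(ws * (q11[sel] + pm1[sel]^2)), 1, 1)
      mom$x_xprev[[k]] <- matrix(sum(ws * (q12[sel] + pm1[sel] * pm2[sel])), 1, 1)
    }
    sm_mean[1, i] <- sum(w * pm2)
    sm_m2[[i]] <- matrix(sum(w * (q22 + pm2^2)), 1, 1)
    cross[[i]] <- matrix(sum(w * (q12 + pm1 * pm2)), 1, 1)
    red <- reduce_scalar_gaussians(log(pmax(w, 1e-300)), pm2, q22, gamma_s)
    steps[[i]] <- gm_belief(exp(red$lw - logsumexp(red$lw)),
                            matrix(red$m, 1), lapply(red$P, function(v)
                              matrix(v, 1, 1)), cap = gamma_s)
  }
  mom$e0 <- e0
  structure(list(steps = steps, means = sm_mean, second_moments = sm_m2,
                 cross_moments = cross, e0 = e0, moments = mom,
                 approx_loglik = loglik, caps = caps, K = K, model = model),
            class = "gm_smoothed")
}

# Scalar-Gaussian mixture reduction (top cap-1 kept, remainder
# moment-matched), on (log-weight, mean, variance) vectors.
reduce_scalar_gaussians <- function(lw, m, P, cap) {
  C <- length(lw)
  if (!is.finite(cap) || C <= cap) return(list(lw = lw, m = m, P = P))
  ord <- order(lw, decreasing = TRUE)
  keep <- ord[seq_len(cap - 1L)]
  rest <- ord[cap:C]
  lt <- logsumexp(lw[rest])
  if (lt < -745)
    return(list(lw = lw[keep], m = m[keep], P = P[keep]))
  wr <- exp(lw[rest] - lt)
  mu <- sum(wr * m[rest])
  Pm <- sum(wr * (P[rest] + (m[rest] - mu)^2))
  list(lw = c(lw[keep], lt), m = c(m[keep], mu), P = c(P[keep], Pm))
}

# Scalar canonical-form reduction, ranked by total mass (log-integral when
# proper, log-scale otherwise); surplus merged moment-matched when proper.
reduce_scalar_canonical <- function(L, h, g, cap) {
  C <- length(L)
  if (!is.finite(cap) || C <= cap) return(list(L = L, h = h, g = g))
  proper <- L > 1e-12
  mass <- ifelse(proper,
                 g + h^2 / (2 * pmax(L, 1e-12)) + 0.5 * log(2 * pi) -
                   0.5 * log(pmax(L, 1e-12)),
                 g)
  ord <- order(mass, decreasing = TRUE)
  keep <- ord[seq_len(cap - 1L)]
  rest <- ord[cap:C]
  rp <- rest[proper[rest]]
  if (!length(rp)) return(list(L = L[keep], h = h[keep], g = g[keep]))
  lt <- logsumexp(mass[rp])
  wr <- exp(mass[rp] - lt)
  means <- h[rp] / L[rp]
  vars <- 1 / L[rp]
  mu <- sum(wr * means)
  Pm <- sum(wr * (vars + (means - mu)^2))
  Lm <- 1 / Pm; hm <- mu / Pm
  gm <- lt - (hm^2 / (2 * Lm) + 0.5 * log(2 * pi) - 0.5 * log(Lm))
  list(L = c(L[keep], Lm), h = c(h[keep], hm), g = c(g[keep], gm))
}
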