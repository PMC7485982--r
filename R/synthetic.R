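#' Scenario specification for the synthetic cocktail-party simulation
#'
#' Defines a two-speaker attention-switching trial: the listener's attention
#' alternates between the speakers on a fixed schedule, the TRF of each
#' speaker carries an attention-independent M50 component, an
#' attention-modulated M100 component (larger magnitude when that speaker is
#' attended), and a slowly varying high-latency component near 200 ms. The
#' defaults reproduce the reference simulation geometry: a 90 s trial at
#' 100 Hz, 250 ms TRFs over five Gaussian atoms (width 18 ms, centers
#' 50 ms apart from 0 — narrow enough for distinct M50/M100 peaks and a
#' well-conditioned dictionary), 300 ms state windows (N = 300), one mixture
#' label per
#' 1.5 s (W = 5), attention switching every 15 s starting at 7.5 s, and
#' transition coefficient 0.99.
#'
#' @param duration_s Trial length in seconds.
#' @param F_s Sampling rate (Hz).
#' @param t0_s State-window length in seconds.
#' @param W Label-window length in state windows.
#' @param switch_every_s,first_switch_s Attention-switch schedule.
#' @param trf_length_s,atom_spacing_s,atom_variance_s2 Dictionary geometry.
#' @param alpha Transition coefficient of the estimation model.
#' @param snr_db Nominal observation SNR, \eqn{10\log_{10}(\bar E/\sigma^2)}.
#' @param m50_level M50 state level (both speakers, constant up to jitter).
#' @param m100_attended,m100_unattended M100 state levels (negative; the
#'   attended magnitude is twice the unattended one by default, matching the
#'   qualitative attended/unattended contrast).
#' @param late_amplitude,late_period_s Amplitude and period of the
#'   attention-independent 200 ms component oscillation.
#' @param ramp_s Half-cosine ramp duration at attention switches.
#' @param m50_jitter_sd Standard deviation of the small within-mode jitter
#'   applied to every active component coordinate (named after the M50, where
#'   it is the only source of variation).
#' @param seed Seed for every stochastic ingredient.
#' @return List of class `scenario_spec`.
#' @export
scenario_spec <- function(duration_s = 90, F_s = 100, t0_s = 0.3, W = 5L,
                          switch_every_s = 15, first_switch_s = 7.5,
                          trf_length_s = 0.25, atom_spacing_s = 0.05,
                          atom_variance_s2 = 0.018^2, alpha = 0.99,
                          snr_db = 6.7,
                          m50_level = 1, m100_attended = -2,
                          m100_unattended = -1, late_amplitude = 0.75,
                          late_period_s = 45, ramp_s = 1.5,
                          m50_jitter_sd = 0.01, seed = 1L) {
  t0 <- round(t0_s * F_s)
  N <- round(duration_s * F_s / t0)
  if (abs(N * t0 - duration_s * F_s) > 1e-6)
    stop_dyntrf("duration must be divisible by the window length")
  if (N %% W != 0L)
    stop_dyntrf("N = %d state windows not divisible by W = %d", N, W)
  structure(list(duration_s = duration_s, F_s = F_s, t0 = t0, t0_s = t0_s,
                 W = as.integer(W), N = as.integer(N),
                 switch_every_s = switch_every_s,
                 first_switch_s = first_switch_s,
                 trf_length_s = trf_length_s, atom_spacing_s = atom_spacing_s,
                 atom_variance_s2 = atom_variance_s2, alpha = alpha,
                 snr_db = snr_db, m50_level = m50_level,
                 m100_attended = m100_attended,
                 m100_unattended = m100_unattended,
                 late_amplitude = late_amplitude,
                 late_period_s = late_period_s, ramp_s = ramp_s,
                 m50_jitter_sd = m50_jitter_sd, seed = seed),
            class = "scenario_spec")
}

#' Surrogate band-limited speech envelope
#'
#' Stand-in for a real speech envelope: Gaussian noise band-passed to the
#' requested band, rectified, log-transformed, band-passed again (so the
#' final series has its spectral mass inside the band, mirroring the 2-8 Hz
#' filtering applied to real envelopes), and standardized. The band-pass is
#' an FFT mask with exact band edges. Deterministic per seed.
#'
#' @param duration_s Duration in seconds.
#' @param F_s Sampling rate (Hz).
#' @param band Pass band in Hz (default 2-8 Hz, the slow temporal
#'   modulations of speech).
#' @param seed RNG seed.
#' @return Numeric envelope of length `duration_s * F_s` (empty for zero
#'   duration).
#' @export
synth_envelope <- function(duration_s, F_s = 100, band = c(2, 8), seed = 1L) {
  if (band[2] > F_s / 2) stop_dyntrf("band edge %g Hz above Nyquist %g Hz",
                                     band[2], F_s / 2)
  Tn <- round(duration_s * F_s)
  if (Tn == 0L) return(numeric(0))
  with_seed(seed, {
    x <- stats::rnorm(Tn)
    x <- fft_bandpass(x, F_s, band)
    x <- log1p(abs(x))
    x <- fft_bandpass(x, F_s, band)
    as.numeric(scale(x))
  })
}

# Brick-wall FFT band-pass filter.
fft_bandpass <- function(x, F_s, band) {
  Tn <- length(x)
  freqs <- (seq_len(Tn) - 1) * F_s / Tn
  freqs <- pmin(freqs, F_s - freqs)
  keep <- freqs >= band[1] & freqs <= band[2]
  Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / Tn
}

#' Synthesize ground-truth TRF state trajectories
#'
#' Builds per-window states (not generated from the state-space model): the
#' M50 coordinate of both speakers stays constant up to small jitter, the
#' M100 coordinate ramps between the attended and unattended levels at each
#' attention switch (half-cosine ramps of `ramp_s` seconds), and the 200 ms
#' coordinate follows a slow attention-independent oscillation (opposite
#' phase across speakers). Remaining atoms are zero.
#'
#' @param spec A [scenario_spec()].
#' @return List with `states` (`2D x N`), `dict`, `attention` (attended
#'   speaker 1/2 per window), `labels_window` (attended speaker per label
#'   window, majority vote), `time_s`.
#' @export
synth_trf_trajectory <- function(spec) {
  dict <- build_dictionary(spec$F_s, spec$trf_length_s, spec$atom_spacing_s,
                           spec$atom_variance_s2)
  D <- dict$D
  N <- spec$N
  tw <- (seq_len(N) - 0.5) * spec$t0_s        # window centers, seconds
  switches <- if (spec$first_switch_s < spec$duration_s)
    seq(spec$first_switch_s, spec$duration_s - 1e-9,
        by = spec$switch_every_s) else numeric(0)
  # attended speaker per window: speaker 1 first, toggling at each switch
  att <- 1L + (findInterval(tw, switches) %% 2L)
  # attention weight of speaker 1 in [0, 1] with half-cosine ramps
  a1 <- as.numeric(att == 1L)
  if (spec$ramp_s > 0) {
    for (s in switches) {
      idx <- which(tw >= s - spec$ramp_s / 2 & tw <= s + spec$ramp_s / 2)
      if (!length(idx)) next
      phase <- (tw[idx] - (s - spec$ramp_s / 2)) / spec$ramp_s
      before <- a1[max(min(idx) - 1L, 1L)]
      target <- 1 - before
      a1[idx] <- before + (target - before) * (1 - cos(pi * phase)) / 2
    }
  }
  i_m50 <- which.min(abs(dict$atom_centers - 0.05))
  i_m100 <- which.min(abs(dict$atom_centers - 0.10))
  i_200 <- which.min(abs(dict$atom_centers - 0.20))
  lvl <- function(w) spec$m100_unattended +
    w * (spec$m100_attended - spec$m100_unattended)
  states <- matrix(0, 2L * D, N)
  # small within-mode variability on every active coordinate: real neural
  # trajectories are never exactly constant, and the oracle mixture fit on
  # the process-noise residuals needs proper (non-degenerate) modes
  jit <- with_seed(spec$seed, matrix(stats::rnorm(6 * N, 0, spec$m50_jitter_sd),
                                     6, N))
  states[i_m50, ] <- spec$m50_level + jit[1, ]
  states[D + i_m50, ] <- spec$m50_level + jit[2, ]
  states[i_m100, ] <- lvl(a1) + jit[3, ]
  states[D + i_m100, ] <- lvl(1 - a1) + jit[4, ]
  osc <- spec$late_amplitude *
    (cos(2 * pi * tw / spec$late_period_s) - 1)   # in [-2A, 0]
  states[i_200, ] <- osc + jit[5, ]
  states[D + i_200, ] <- spec$late_amplitude *
    (cos(2 * pi * tw / spec$late_period_s + pi) - 1) + jit[6, ]
  list(states = states, dict = dict, attention = att,
       labels_window = att[seq(1L, N, by = spec$W) + (spec$W %/% 2L)],
       time_s = tw, a1 = a1)
}

#' Render noisy observations at a requested nominal SNR
#'
#' Computes the noiseless response \eqn{y_t = s_t^\top \tilde\tau_t} from
#' the truth states and envelopes, solves
#' \eqn{\sigma^2 = \bar E \cdot 10^{-SNR/10}} from the trial-average signal
#' power \eqn{\bar E}, and adds i.i.d. Gaussian noise.
#'
#' @param truth Output of [synth_trf_trajectory()].
#' @param design A [build_design()] over the envelopes.
#' @param snr_db Requested nominal SNR in dB.
#' @param seed RNG seed for the noise.
#' @return List with `y` (noisy response), `signal` (noiseless response),
#'   `sigma2`, `snr_realized_db`.
#' @export
render_observations <- function(truth, design, snr_db, seed = 1L) {
  maps <- design_obs_maps(design, truth$dict)
  N <- design$N
  signal <- numeric(N * design$t0)
  for (n in seq_len(N))
    signal[((n - 1) * design$t0 + 1):(n * design$t0)] <-
      as.numeric(maps[[n]] %*% truth$states[, n])
  Ebar <- mean(signal^2)
  if (Ebar <= 0) stop_dyntrf("all-zero signal: SNR undefined")
  sigma2 <- Ebar * 10^(-snr_db / 10)
  noise <- with_seed(seed, stats::rnorm(length(signal), 0, sqrt(sigma2)))
  y <- signal + noise
  list(y = y, signal = signal, sigma2 = sigma2,
       snr_realized_db = 10 * log10(Ebar / mean(noise^2)))
}

#' Simulate a complete synthetic cocktail-party trial
#'
#' Runs the full generator: surrogate envelopes, truth TRF trajectories,
#' design matrices, SNR-controlled observations, oracle process-noise samples
#' \eqn{\hat w_n = x_n - \alpha x_{n-1}}, and window attention labels.
#'
#' @param spec A [scenario_spec()].
#' @return Object of class `scenario_truth`: everything needed to fit and
#'   score the estimators (`states`, `dict`, `design`, `envelopes`, `y`,
#'   `sigma2`, `attention`, `oracle_w`, `snr_realized_db`, `spec`).
#' @export
simulate_scenario <- function(spec = scenario_spec()) {
  env1 <- synth_envelope(spec$duration_s, spec$F_s, seed = spec$seed)
  env2 <- synth_envelope(spec$duration_s, spec$F_s, seed = spec$seed + 1000L)
  truth <- synth_trf_trajectory(spec)
  design <- build_design(cbind(env1, env2), spec$F_s, truth$dict$L, spec$t0)
  obs <- render_observations(truth, design, spec$snr_db,
                             seed = spec$seed + 2000L)
  X <- truth$states
  oracle_w <- X[, -1, drop = FALSE] - spec$alpha * X[, -ncol(X), drop = FALSE]
  structure(list(spec = spec, states = X, dict = truth$dict, design = design,
                 envelopes = cbind(env1, env2), y = obs$y,
                 signal = obs$signal, sigma2 = obs$sigma2,
                 snr_realized_db = obs$snr_realized_db,
                 attention = truth$attention,
                 labels_window = truth$labels_window, a1 = truth$a1,
                 time_s = truth$time_s, oracle_w = oracle_w),
            class = "scenario_truth")
}

#' Oracle Gaussian-mixture fit to the true process-noise samples
#'
#' Maximum-likelihood GM fit (sample-space EM) to the oracle residuals
#' \eqn{\hat w_n = x_n - \alpha x_{n-1}} computed from the true states —
#' available only in simulation, where it serves as the reference the
#' state-space EM should recover. When several candidate component counts are
#' given, the best BIC fit is chosen.
#'
#' @param truth A `scenario_truth` (or any `d x N` residual matrix via
#'   `oracle_w`).
#' @param M_candidates Candidate component counts.
#' @param diagonal Diagonal component covariances.
#' @param seed Seed for the sample-space EM.
#' @return List with `probs`, `means`, `covs`, `chosen_M`, `loglik`.
#' @export
oracle_gm_fit <- function(truth, M_candidates = 3, diagonal = TRUE, seed = 1L) {
  W <- if (inherits(truth, "scenario_truth")) truth$oracle_w else as.matrix(truth)
  samples <- t(W)
  best <- NULL
  for (M in M_candidates) {
    fit <- gm_fit_samples(samples, M, diagonal = diagonal, seed = seed)
    bic <- fit$mclust$bic
    if (is.null(best) || bic > best$bic) best <- c(fit, list(bic = bic, M = M))
  }
  list(probs = best$probs, means = best$means, covs = best$covs,
       chosen_M = best$M, loglik = best$loglik)
}

#' Count modes of a one-dimensional Gaussian-mixture density
#'
#' Evaluates the mixture density on a fine grid spanning the components and
#' counts strict local maxima. Used to verify that the oracle residuals along
#' the attended M100 coordinate are multimodal.
#'
#' @param probs,means,vars Mixture parameters (1-D).
#' @param n_grid Grid resolution.
#' @return Integer mode count.
#' @export
count_gm_modes <- function(probs, means, vars, n_grid = 2000L) {
  sd <- sqrt(vars)
  lo <- min(means - 4 * sd); hi <- max(means + 4 * sd)
  g <- seq(lo, hi, length.out = n_grid)
  dens <- rowSums(vapply(seq_along(probs), function(m)
    probs[m] * stats::dnorm(g, means[m], sd[m]), numeric(n_grid)))
  interior <- 2:(n_grid - 1)
  sum(dens[interior] > dens[interior - 1] & dens[interior] > dens[interior + 1])
}

#' Normalized root-mean-square error between state trajectories
#'
#' Frobenius-relative error \eqn{\|\hat X - X\|_F / \|X\|_F} over the full
#' trajectory.
#'
#' @param estimated,truth `d x N` state matrices of matching shape.
#' @return Non-negative scalar.
#' @export
normalized_rmse <- function(estimated, truth) {
  estimated <- as.matrix(estimated); truth <- as.matrix(truth)
  if (!identical(dim(estimated), dim(truth)))
    stop_dyntrf("state matrices have different shapes")
  sqrt(sum((estimated - truth)^2)) / sqrt(sum(truth^2))
}
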