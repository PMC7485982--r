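# dyntrf

Dynamic estimation of auditory temporal response functions (TRFs) with
linear state-space models whose process noise is a **windowed Gaussian
mixture**, fitted by EM from the observations alone.

## The problem

In a cocktail-party experiment a listener attends to one of two concurrent
speakers while a single-channel auditory response is recorded. The TRF — the
time-varying kernel that convolves each speaker's speech envelope into the
neural response — carries attention markers: a stable positive M50 peak
(~50 ms lag) and a negative M100 peak (~100 ms lag) whose magnitude is
larger for the attended speaker. Tracking TRFs over time means estimating a
latent state sequence whose dynamics are *heterogeneous*: components rise,
fall, and hold in recurring modes as attention switches. A single Gaussian
process noise blurs these modes; `dyntrf` models them explicitly.

## The model

$$x_n = \alpha\, x_{n-1} + w_n, \qquad y_n = S_n^\top \tilde G\, x_n + v_n,
\qquad v_n \sim N(0, \sigma^2 I),$$

where $x_n$ holds the dictionary coefficients of both speakers' TRFs
($\tau_n = \tilde G x_n$) and the process noise follows a windowed Gaussian
mixture: one latent label $z_i \sim \mathrm{Cat}(p_{1:M})$ per window of $W$
state steps, and $w_n \sim N(\mu_{z_i}, \Sigma_{z_i})$ within the window.
The mixture parameters (and optionally $\sigma^2$, $\alpha$) are estimated
by EM with two interchangeable E-step approximations:

* **closed form** — a two-filter Gaussian-sum smoother over label-window
  blocks with mixture reduction (exact when the reduction caps are
  unbounded);
* **sequential Monte Carlo** — bootstrap particle smoothing over the same
  blocks with backward reweighting.

Benchmarks (regularized RLS with a forgetting factor; a Markov-switching
AR(1) model on least-squares surrogate states), M100-based attention
decoding, AIC model-order selection, inverse-gamma MAP regularization, and
a synthetic cocktail-party generator are included.

## Worked example

```r
library(dyntrf)

# a 90 s two-speaker trial: attention switches every 15 s, nominal SNR 6.7 dB
tr <- simulate_scenario(scenario_spec(snr_db = 6.7, seed = 1))

# fit the GM process-noise model (M = 3 components, one label per 1.5 s)
cfg <- em_config(max_iters = 40, diagonal_only = TRUE,
                 init_strategy = "residual-gm-fit", seed = 1)
fit <- fit_trf_ssm(tr$design, tr$y, tr$dict, backend = "gm", M = 3,
                   W = tr$spec$W, alpha = 0.99, config = cfg)
fit$trf
#> trf_series [gm-ssm(M=3)]: 25 lags x 300 windows, F_s = 100 Hz

normalized_rmse(fit$trf$states, tr$states)
#> [1] 0.06191492

# decode attention from the M100 magnitude difference
m100 <- extract_m100(fit$trf)
dec <- decode_attention(m100$difference, tr$attention)
dec$misclassification_rate
#> [1] 2
```

The fitted states track the true TRF trajectories to within a 6%
Frobenius-relative error, and the sign of the M100 magnitude difference
recovers the attended speaker in 98% of the 300 state windows (the errors
sit at the attention-switch ramps, where neither speaker dominates).

A command-line surface wraps the same functions
(`inst/cli/dyntrf simulate|fit|select-model|decode|benchmark`); see
`?trf_cli`.

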