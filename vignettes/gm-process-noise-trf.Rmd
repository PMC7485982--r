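---
title: "State-space models with Gaussian-mixture process noise for dynamic TRF estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-space models with Gaussian-mixture process noise for dynamic TRF estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`dyntrf` estimates latent linear dynamics whose driving noise is *not* a
single Gaussian. The state equation is

$$x_n = \alpha x_{n-1} + w_n, \qquad y_n = A_n x_n + v_n,$$

with a scalar transition coefficient $\alpha \in (0,1]$, per-window
observation maps $A_n$ (each window carries $t_0$ samples), and i.i.d.
Gaussian observation noise $v_n \sim N(0, \sigma^2 I)$. The process noise is
a *windowed Gaussian mixture*: time is cut into $K = N/W$ label windows of
$W$ consecutive state steps; window $i$ draws a latent label
$z_i \sim \mathrm{Cat}(p_{1:M})$ i.i.d., and within the window
$w_n \sim N(\mu_{z_i}, \Sigma_{z_i})$. With $M = 1$ this is the ordinary
linear-Gaussian state-space model; with $W = 1$ it approximates an arbitrary
i.i.d. multimodal process noise. The windowed form captures dynamics that
*switch between recurring local modes* — in the auditory application, TRF
components that rise, fall, or hold over stretches of a second or two.

Parameters $\Theta = \{p_{1:M}, \mu_{1:M}, \Sigma_{1:M}\}$ (plus optionally
$\sigma^2$ and $\alpha$) are estimated by maximum likelihood via EM. The
E-step needs expectations of membership-weighted state moments,

$$\hat\epsilon_{i,m} = P(z_i = m \mid x_{1:N}, \Theta) \propto
p_m \prod_{j=1}^{W} N(v_{(i,j)};\, \mu_m, \Sigma_m),$$

with $v_{(i,j)} = x_{(i,j)} - \alpha x_{(i,j-1)}$, which are intractable in
closed form because $\hat\epsilon$ is a nonlinear function of the
trajectory. Two approximations are provided:

* **Closed form** (`closed_form_e_step()`): a two-filter Gaussian-sum
  smoother over *label-window blocks*. The extended block state
  $\xi_i = (x_{(i,0)}, \ldots, x_{(i,W)})$ of dimension $(W+1)d$ makes the
  model a switching linear-Gaussian SSM with i.i.d. labels at the block
  level. A forward Gaussian-sum filter branches over the $M$ components per
  block and reduces to at most $\Gamma_F$ components; a backward
  information-form message (cap $\Gamma_B$) is combined with the tagged
  forward components in canonical form, yielding per-window label posteriors
  and per-label Gaussian mixtures over the whole block — which contain the
  within-window one-step cross-covariances the M-step needs. The block
  formulation is what makes the algorithm *exact when the caps are
  unbounded*; a per-step mixture branching would not be, for $W > 1$,
  because the forward past and backward future of a step share the current
  window's label.
* **Sequential Monte Carlo** (`particle_smoother()` + `mc_e_step()`): a
  bootstrap filter over the same per-window blocks (one label draw per
  particle per window, systematic resampling when the effective sample size
  falls below $U/2$), followed by backward reweighting across adjacent
  blocks. Because blocks overlap in one state, only the first within-block
  transition couples them, so the $O(U^2)$ backward kernel is a
  $d$-dimensional Gaussian density.

Both backends deliver the same moment set (`e0`, `e1`, `e2` and the
cross-moment blocks), consumed by the closed-form M-step
(`m_step_update()`, `update_sigma2()`, `update_alpha()`). A third backend,
`enumerate_label_sequences()`, computes the E-step exactly by enumerating
all $M^K$ label sequences; it is the test oracle and is guarded to
$M^K \le 10^4$.

## Numerical choices

* All mixture weights are handled in log space with log-sum-exp; mixture
  reduction keeps the highest-weight components and merges the surplus into
  its moment-matched Gaussian, so the first two moments of discarded mass
  are conserved. Backward (information-form) components are ranked by their
  total mass (log-integral) when proper.
* Covariances are symmetrized after every update with an eigenvalue floor of
  `1e-10`; measurement updates use the information form when a window
  carries at least $d$ samples (positive definite by construction) and a
  Joseph-form update otherwise.
* The initial state prior is $N(0, 10 I)$ by default and configurable; it
  matters only for very short series. The initial state is smoothed along
  with the trajectory, so the first window's transition uses its exact
  posterior rather than the prior mean.
* Convergence: relative change of the (approximate) log-likelihood below
  `1e-6`, capped at 200 iterations.
* A dedicated scalar fast path ($d = 1$, $W = 1$, $t_0 = 1$) unrolls the
  block algebra to vectorized arithmetic; it is dispatch-transparent and
  tested for equality against the generic path.

## Initialization and regularization

Two initializations are provided (`initialize_gm()`). *Broad-random* sets
uniform probabilities, all covariances equal to the Gaussian-SSM
process-noise estimate, and random means with standard deviation half the
broad covariance scale — small relative to the component spread, but enough
to break the symmetric EM fixed point at which identical components are
stationary. *Residual-GM-fit* fits a sample-space Gaussian mixture (via
mclust) to the residuals $\hat w_n = \hat x_n^{(s)} - \alpha \hat
x_{n-1}^{(s)}$ of the Gaussian-SSM smoothed states; it converges in far
fewer iterations and is the preferred start at low SNR. With $M = 1$ and the
broad-random strategy no Gaussian pre-fit is run: a single-component mixture
EM *is* Gaussian EM, and the two code paths then agree iteration for
iteration, which is also how the package verifies itself.

For real recordings, inverse-gamma MAP priors on the covariance diagonals
(`ig_prior()`, strength $\kappa = N$ for the Gaussian model, $N/M$ for the
mixture) and mixture-mean bounding (`bound_means()`, shrinking component
means toward their weighted mean until the total mixture variance respects
the Gaussian-SSM estimate) restrict the dynamic range of the process noise.
The prior hyperparameters can be tuned from RLS residuals
(`ig_prior_from_residuals()`): the prior mode is set to the per-dimension
empirical residual variance with a fixed shape of 2. Two cautions from this
package's own experiments: (i) estimating a free process-noise *mean* in the
Gaussian baseline is dangerous when the observation maps have weakly
identified directions, because a mean drift $\bar\mu$ is amplified to a
stationary level $\bar\mu/(1-\alpha)$ — the Gaussian baseline is therefore
zero-mean by default; (ii) a strong variance prior pins all mixture
components to the same scale and erases the mixture's advantage, so the
simulation benchmark runs without priors.

Model order is chosen by AIC (`aic_select()`): $2k - 2\hat\ell$ with
$\hat\ell$ the approximate log-likelihood from the forward normalization
constants and $k$ counting $M-1$ probabilities, $Md$ means, $Md$ diagonal
variances ($Md(d+1)/2$ for full covariances), plus $\sigma^2$ and $\alpha$
when estimated. Ties break toward the smaller model.

## The TRF application

The auditory response $y_t$ to two concurrent speech streams is modeled as
$y_t = s_t^\top \tilde\tau_t + v_t$, where $s_t$ stacks the $L$ most recent
log-envelope samples of both speakers and $\tilde\tau_t$ the two temporal
response functions (TRFs). TRFs are piecewise constant over windows of
$t_0$ samples and represented on a Gaussian lag dictionary,
$\tau_n = \tilde G x_n$, giving observation maps $A_n = S_n^\top \tilde G$.
Dictionary columns are unnormalized Gaussian kernels; any global scale is
absorbed by the states, and a scale-consistency test guards this choice.

One deliberate parameter interpretation: atom "variances" of 0.018 s² at
50 ms spacing (or 8.5·10⁻³ s² at 20 ms spacing) would give atom widths of
134 ms and 92 ms — dictionaries with condition
numbers of 2·10⁴ and 2·10¹⁵, under which states are unidentifiable and the
characteristic separate M50/M100 peaks cannot be represented. The package
reads those numbers as atom *widths* (standard deviations) in seconds; the
scenario default is therefore an atom variance of $(0.018)^2$ s², giving a
well-conditioned dictionary (condition number 1.4). `build_dictionary()`
itself takes whatever variance it is given.

Benchmarks: regularized RLS (`rls_fit()`, forgetting factor $\lambda$,
$\ell_2$ or $\ell_1$ penalty, two-fold cross-validated weight via
`choose_gamma()` — contiguous halves, both directions averaged, ties to the
larger penalty) and a Markov-switching AR(1) model (`msar_fit()`) fitted by
Baum–Welch on the $\lambda = 0$ least-squares surrogate states, with
k-means-on-innovations initialization and causal regime-averaged one-step
estimates (`msar_estimate()`).

Attention decoding uses the M100: per speaker and window the magnitude of
the most negative TRF value in the closed lag interval [0.1, 0.2] s
(`extract_m100()`); if no negative deflection exists the magnitude of the
smallest positive value is used and flagged in the output — a documented
convention for a case the decoding rule does not otherwise define. Decisions
compare the speaker-1-minus-speaker-2 difference with zero at the state
window rate; an exact zero counts as misclassified (`decode_attention()`).

## The synthetic scenario

`simulate_scenario()` emulates a 90 s two-speaker trial at 100 Hz: the
listener's attention alternates every 15 s starting at 7.5 s; each speaker's
TRF carries a constant positive M50, an attention-modulated negative M100
(attended level −2, unattended −1, i.e. a 2:1 magnitude contrast), and a
slow attention-independent oscillation of the 200 ms component
(period 45 s, opposite phase across speakers). Switches ramp over 1.5 s with
a half-cosine (one label window), making switch windows genuinely
heterogeneous. Every active coordinate carries small jitter (sd 0.01):
real trajectories are never exactly constant, and without it the oracle
process-noise residuals are point masses on which a maximum-likelihood GM
fit is ill-posed. The trajectories are deliberately *not* generated from the
state-space model being fitted.

Stimulus envelopes are surrogate: rectified band-limited noise,
log-transformed and band-passed to 2–8 Hz with an exact FFT mask, then
standardized. They share the second-order band structure of slow speech
modulations but none of speech's higher-order statistics — so passing tests
demonstrate correct estimation under the assumed model class, not
performance on real MEG. Observations are rendered at a nominal SNR
$10\log_{10}(\bar E/\sigma^2)$ with $\bar E$ the trial-average power of the
noiseless response; the realized SNR stays within ±0.5 dB on 90 s trials.

The normalized RMSE reported by `normalized_rmse()` is the
Frobenius-relative error $\|\hat X - X\|_F / \|X\|_F$ over the full state
trajectory — the normalization is this package's own definition, so its
values are comparable only within the package.

Oracle multimodality (the reference check that the generator produces
mixture-like dynamics) is assessed with a maximum-likelihood GM fit at the
scenario's putative component count of three (hold / rise / fall) along the
attended M100 coordinate; an information-criterion-chosen component count
tends to merge the rare ramp modes into one broad component under the
half-cosine ramp.

## Problem sizes and what the tests show

The validation suite runs the full default scenario ($d = 10$, $N = 300$,
$K = 60$) for the estimator comparison (five trials at 0 dB, 40 EM
iterations with the residual-GM start), scalar instances ($K = 100$) for
parameter recovery and model selection (10–20 trials), enumeration-oracle
instances with $M^K \le 81$, and $U = 2\cdot10^4$ particles for the
SMC-vs-enumeration agreement. These sizes were chosen so that each property
is decided by its median over independent trials rather than a single run.
Passing them shows: exactness of the closed-form E-step in the uncapped
limit, statistical consistency of the SMC E-step, EM monotonicity under the
exact E-step, recoverability of separated mixtures at informative SNR, the
expected estimator ordering on the cocktail-party scenario, and that AIC
prefers a mixture over a single Gaussian whenever the data carry one. They
do not show robustness to model mismatch beyond what the scenario contains
(no artifacts, no non-Gaussian observation noise, no real speech).

## Known limitations

* The closed-form backend requires the linear model; nonlinear dynamics
  would need linearization, which is out of scope.
* Capped Gaussian-sum smoothing has no error guarantee; the approximate
  log-likelihood may err in either direction, and the package asserts only
  structural sanity (normalized weights, finite moments) under reduction.
* The mixture EM inherits the usual EM pathologies: symmetric saddles under
  broad initialization (mitigated, not eliminated, by the randomized means)
  and local optima; medians over seeds are the intended summary.
* MSAR estimation operates on a least-squares surrogate of the states, not
  on the observations; its regime decoding degrades when regimes are not
  well separated in their AR coefficients or innovation statistics.
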