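---
title: "Personalized state-space modelling of wearable biosensor streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized state-space modelling of wearable biosensor streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearssm)
```

## The problem

Two weeks of free-living wearable data — interstitial glucose every 15
minutes from a CGM, physical activity counts, heart rate (HR) and heart
rate variability (HRV, as RMSSD) from a chest-worn device, plus a
timestamped meal log — contain far more physiology than the standard
summary statistics (coefficient of variation, time in range, 2-h
postprandial windows) extract. `wearssm` fits continuous-time linear
Gaussian state-space models to the *entire* multichannel recording and
returns a small set of interpretable personal parameters with full
posterior uncertainty: how fast glucose returns to baseline after a meal
(response half-life), whether the return overshoots (damping
coefficient), how large meal excursions are (per-label meal heights), the
amplitude and peak time of a 24-h baseline glucose rhythm, how strongly
activity drives HR and HRV, and how much glucose variation the physical
and heart activity channels explain beyond meals and the clock.

## The model family

All three models are instances of one dynamic model,

$$ dx(t) = W\,x(t)\,dt + d\beta, \qquad \operatorname{Cov}(d\beta) = Q\,dt, $$

observed at discrete, possibly irregular times through

$$ y(t_k) = H\,x(t_k) + \mathcal N(m_k, R). $$

Because the dynamics are linear and Gaussian, the transition over any step
$\Delta$ is *exact*: $F = e^{W\Delta}$ and
$\Sigma = \int_0^\Delta e^{Ws} Q e^{W^\top s}\,ds$, computed by the Van
Loan matrix-fraction decomposition (`discretize()`), never by an Euler
scheme. The likelihood is then the product of one-step predictive
densities from the Kalman filter (`kalman_filter()`), with missing
channels handled by row deletion and fully missing steps contributing
prediction only.

**Glucose (Model 1).** A 2-D system with drift
$W = \begin{pmatrix} -A_{11} & -A_{12} \\ A_{21} & -A_{22} \end{pmatrix}$
(all rates positive, hence stable) and process noise only on the observed
glucose component ($Q = \mathrm{diag}(0, B_{22})$). The latent first
component provides negative feedback, standing in for insulin action.
Each logged ingestion event perturbs the latent component; the resulting
deterministic glucose-channel impulse response, rescaled to peak at the
event label's *meal height* $h_j$ (mmol/L above baseline), enters the
observation mean, and meals superpose linearly. Events sharing a
normalized annotation share one height parameter. A sinusoidal baseline
$g(t) = A_0 + A_1\,(1 + \cos(\omega t - \omega\varphi))/2$ with
$\omega = 2\pi/24$ fixed adds the circadian component: $A_0$ is the
trough, $A_1$ the peak-to-trough amplitude, $\varphi$ the peak clock
hour.

From the fitted drift, two shape metrics follow. The *damping
coefficient* $-\det(W - I\,\mathrm{tr}(W)/2)/(\mathrm{tr}(W)/2)^2$ is
negative exactly when the eigenvalues are complex (underdamped: the
response dips below baseline), positive when real and distinct
(overdamped, monotone return) and zero at critical damping. The *response
half-life* is the time for the unit-peak response to fall from 1 to
0.5 mmol/L, measured from the peak, found by bracketing and root
refinement to $10^{-6}$ h.

**Activity/HR/HRV (Model 2).** A 3-D system on SD-normalized channels
(HRV enters as RMSSD$^{-1}$) with lower-triangular drift: activity
relaxes at rate $C_{11}$ and drives HR ($C_{21}$) and HRV ($C_{31}$).
The HR–HRV diffusion block has off-diagonal
$\rho\sqrt{D_{22} D_{33}}$, so $\rho \in (-1,1)$ is the correlation of
their fluctuations — the quantity of physiological interest, capturing
shared autonomic drive beyond what activity explains. Each channel has
its own sinusoidal baseline.

**Combined (Model 3).** The 5-D concatenation of Models 1 and 2, plus
three unconstrained couplings $C_{51}, C_{52}, C_{53}$ in the drift row
of the observed glucose component, carrying the effect of activity, HR
and HRV on glucose. Following the staged protocol, the Model-2 block is
locked to its fitted values while the glucose parameters and couplings
are estimated.

## Inference

Each participant is fitted independently. The posterior
$p(\theta \mid y) \propto p(\theta)\,p(y \mid \theta)$ is explored by
Hamiltonian Monte Carlo with 5 leapfrog steps after a BFGS search for the
MAP. Sampling is two-stage: a first adaptive chain tunes a global step
size toward 0.75 acceptance; the per-parameter SDs of its draws become
per-coordinate step scales for the final run (reference settings: 4
chains × 10,000 retained draws after 10,000 burn-in, with adaptation
restricted to the first 80% of burn-in). All counts are configurable
(`hmc_config()`); tests and examples run 1 chain with ~1,000 retained
draws, which is enough for the parameter-recovery checks but not for
publication-grade tail quantiles.

Positive parameters are sampled on the log scale, $\rho$ through
$\tanh$, and the circadian peak time on an unconstrained scale whose flat
prior plus the 24-h periodicity of the likelihood make the posterior
well-defined modulo 24; draws are reported in $[0, 24)$.

**Priors.** The study's own prior table is not available, so defaults are
weakly-informative and scale-matched to physiology, and all are
overridable (`default_priors()`): log-normal (median 0.5 h$^{-1}$, sdlog
1) for rates — half-lives of minutes to a day; half-normal (SD 2) for
meal heights, amplitudes, diffusion intensities and noise SDs — a few
mmol/L or normalized units; Normal(5, 2) mmol/L for the glucose baseline;
Normal(0, 1) for the couplings; uniform for $\rho$ and phases.

**Model comparison.** The circadian component is tested per participant
by refitting without it and comparing
$\mathrm{BIC} = k\ln n - 2\ln p(y\mid\hat\theta)$ at the MAP, with $n$
the number of non-missing observations and a decisiveness cutoff of
$2\ln 10 \approx 4.6$; a difference at the boundary counts as decisive.
**Explained variance** is $1 - \operatorname{Var}(y - \tilde y)/
\operatorname{Var}(y)$ per posterior draw, where $\tilde y$ is the
deterministic meal (+ circadian) mean for Model 1, a Kalman-smoothed
conditional expectation given the included channels for Models 2 and 3;
smoothing is the default, filtering is available by flag.

## The synthetic world

`generate_participant()` simulates the streams the devices would record:
14 days by default, CGM every 15 min, activity/HR/HRV every 5 min, 3–5
meals/day at jittered conventional times with a recurring label
vocabulary (so per-label heights are identifiable), exercise bouts as
square-wave inputs into the activity state that propagate through the
couplings, device observation noise, and random gaps (mean 1.5 h, ~0.5
per day per channel). The default glucose truth is mid-range and
deliberately underdamped: damping $-0.5$, half-life 1.5 h (the rate scale
$a = 0.826$ h$^{-1}$ is the unit-rate half-life 1.239 h divided by 1.5),
heights 0.8–1.2 mmol/L, amplitude 0.8 mmol/L peaking at 15:00, CGM noise
0.25 mmol/L, and $B_{22} = 0.15$ giving ~0.3 mmol/L of stationary
between-meal fluctuation. These sit inside the ranges the source study
reports across participants and are *fixed*: they are the stated world
the tests probe, not tuning knobs.

What the generator does **not** emulate: carbohydrate-dependent
absorption kinetics, nonlinear exercise physiology (e.g. falling hepatic
glucose output in long workouts), sensor drift other than what the GP
detrender removes, and annotation noise in meal logs. A green
recovery test therefore establishes that the estimator inverts its own
model class at realistic signal-to-noise — not that the model class is
adequate for any given participant.

## Numerical choices

* $\Sigma(\Delta)$ in the specialized glucose filter uses the identity
  $\Sigma = S_\infty - F S_\infty F^\top$ with $S_\infty$ the stationary
  (Lyapunov) covariance — exact for stable drift and cheap to cache per
  unique step length.
* The initial state is the stationary distribution with mean zero in
  deviation coordinates: for a two-week recording of a stable system the
  start-up transient is negligible and this choice adds no parameters.
* The impulse-response peak is located by a 720-point grid restricted to
  the first positive lobe (for complex eigenvalues) plus golden-section
  refinement; responses are truncated once their envelope falls below
  $10^{-10}$ of the peak. Terms like $e^{hs}\sinh(\mu s)/\mu$ are
  evaluated through $e^{(h\pm\mu)s}$ so stiff (strongly overdamped)
  proposals cannot overflow.
* Covariance updates use the Joseph form with explicit symmetrization;
  inner linear solves refuse approximate solutions, so a numerically
  singular proposal surfaces as $-\infty$ log posterior rather than as a
  silently wrong value.
* The GP detrender (squared-exponential kernel, length scale 48 h) takes
  its observation-noise SD from `sd(diff(y))/sqrt(2)` by default — a
  first-difference estimate that stops the trend from chasing measurement
  noise; it is a tuning input, not an optimized hyperparameter.
* Likelihood gradients for HMC are central finite differences on the
  unconstrained scale (step $10^{-6}$, computed in compiled code). With
  an exactly computed likelihood this is accurate to ~$10^{-9}$ relative
  and costs $2p$ filter passes per gradient.
* Cross-correlations drop missing pairs per lag and mask lags with fewer
  than 3 pairs; a peak at positive lag means glucose lags the weighted
  aux sum.

## Design decisions that were genuinely open

* The exact functional form of the meal response is not printed in the
  available text; the deterministic impulse response of the fitted
  system, peak-normalized so that the height parameter *is* the maximum
  excursion, matches the stated mechanism (a perturbation of the latent
  component) and the "height relative to baseline" reading of the
  metric. Consequence: heights are comparable across participants even
  when response shapes differ.
* The HR–HRV diffusion off-diagonal is read as $\rho\sqrt{D_{22}D_{33}}$;
  the literal product $\rho D_{22} D_{33}$ would not keep the implied
  correlation inside $(-1, 1)$.
* The couplings $C_{5j}$ act on the drift row of the observed glucose
  component (matching their subscripts), so a sustained aux level shifts
  the deterministic glucose steady state by
  $A_{11}\sum_j C_{5j} u_j / (A_{21}A_{12} + A_{11}A_{22})$ — the
  algebra the tests verify.
* Half-life is measured from the response peak, not from the meal time.
* BIC's $n$ counts non-missing scalar observations; the boundary of the
  cutoff is decisive.
* Adherence uses local-midnight day boundaries and requires two meals at
  least 5 h apart; label normalization is lowercase plus whitespace
  collapse, and can be switched off.

## Limitations

Linear dynamics cannot express saturating or state-dependent physiology;
the circadian baseline is a single harmonic; the meal model ignores
content beyond the annotation label; HRV is taken as device-supplied
RMSSD (no beat-interval processing); and the reduced HMC settings used in
the test suite are for recovery checks, not final inference. The
full-scale posterior summaries of the source study require its deposited
data and the reference MCMC protocol, and are out of scope for this
package's offline test surface.
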