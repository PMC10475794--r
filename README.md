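# wearssm

Bayesian state-space modelling of multimodal wearable biosensor data.

## What problem this solves, and for whom

Researchers and clinicians increasingly collect weeks of free-living
physiology: interstitial glucose every 15 minutes from a continuous
glucose monitor (CGM), physical activity counts, heart rate (HR) and
heart rate variability (HRV, RMSSD) from a chest-worn sensor, and a
smartphone meal log. Standard CGM summaries (coefficient of variation,
time in range, 2-hour postprandial windows) ignore most of this signal.
`wearssm` fits the *entire* multichannel time series with continuous-time
linear Gaussian state-space models and returns interpretable personal
parameters with posterior uncertainty — suitable for comparing
individuals, tracking interventions, and quantifying circadian structure.

## The models

One dynamic family, three nested instances:

```
dx(t) = W x(t) dt + dβ,   Cov(dβ) = Q dt        (latent dynamics)
y(t_k) = H x(t_k) + N(m_k, R)                    (device observation)
```

* **Model 1 — glucose.** 2-D drift `W = [-A11 -A12; A21 -A22]` with
  negative feedback via a latent component; each logged meal adds a
  peak-normalized impulse response of height `h_label` (mmol/L) to the
  observation mean, plus a circadian baseline
  `g(t) = A0 + A1 (1 + cos(ωt − ωφ))/2`, `ω = 2π/24`. Derived metrics:
  response **half-life** (time for the unit-peak response to fall to
  0.5 mmol/L after its peak), **damping coefficient**
  `−det(W − I·tr(W)/2)/(tr(W)/2)²` (negative = underdamped/dipping),
  mean **meal height**, circadian **amplitude** and **peak time**.
* **Model 2 — activity/HR/HRV.** 3-D lower-triangular drift (activity
  drives HR and HRV) on SD-normalized channels with HRV as RMSSD⁻¹;
  HR–HRV fluctuation correlation `ρ` enters the diffusion as
  `ρ√(D22·D33)`; per-channel circadian baselines.
* **Model 3 — combined.** The 5-D concatenation with three unconstrained
  couplings `C51, C52, C53` (activity, HR, HRV → glucose), fitted with
  the Model-2 block locked to its posterior means.

Exact SDE discretization (Van Loan matrix-fraction), exact Kalman-filter
likelihoods with per-step missing-channel handling, MAP initialisation
(BFGS), two-stage Hamiltonian Monte Carlo (5 leapfrog steps, 0.75 target
acceptance, per-parameter step scales from a pilot chain), BIC comparison
with a `2 ln 10` cutoff, and explained-variance decompositions
`1 − Var(y−ỹ)/Var(y)` per posterior draw. A synthetic-data module
generates device-realistic participants from known truth for end-to-end
testing and parameter-recovery studies.

## Worked example

```r
library(wearssm)

# simulate a 14-day participant from the default mid-range truth
# (half-life 1.5 h, damping -0.5, heights ~1 mmol/L, amplitude 0.8 mmol/L
#  peaking at 15:00, CGM noise 0.25 mmol/L)
spec <- scenario_spec(seed = 42, model = "glucose")
gen  <- generate_participant(spec)
rec  <- gen$record

# detrend the CGM stream (48-h squared-exponential GP)
rec$series$glucose <- gp_detrend(rec$series$glucose)$detrended

# fit the glucose model: MAP + HMC (reduced draws for the example)
set.seed(42)
fit <- fit_model1(rec, config = hmc_config(n_chains = 1, n_draws = 1000,
                                           n_burnin = 500,
                                           stage1_draws = 300,
                                           stage1_burnin = 300))
print(fit)
#> <model1_fit: circadian, 1000 draws, BIC 996.7>
#>     half_life damping mean_meal_height circadian_amplitude circadian_peak_time
#> 5%      1.377  -0.825            0.986               0.658              14.734
#> 25%     1.468  -0.527            1.036               0.737              15.053
#> 50%     1.527  -0.355            1.074               0.789              15.329
#> 75%     1.601  -0.216            1.115               0.840              15.549
#> 95%     1.701  -0.057            1.164               0.918              15.961

cmp <- model1_bic_comparison(rec)
cat(sprintf("delta BIC = %.1f -> %s\n", cmp$delta, cmp$verdict))
#> delta BIC = 58.5 -> full
```

Read the table as posterior percentiles of the personal metrics: this
simulated participant clears glucose with a half-life of ~1.5 h (truth
1.5), shows underdamped (dipping) meal responses (damping median −0.36,
90% interval excluding +), ~1.07 mmol/L average meal excursions, and a
~0.8 mmol/L circadian baseline peaking mid-afternoon — and the BIC
difference of 58.5 (≫ 4.6) decisively supports the circadian component
that the generator indeed contained.

The command-line pipeline mirrors this:

```sh
Rscript -e 'wearssm::wearssm_cli()' simulate --preset underdamped --out data --seed 42
Rscript -e 'wearssm::wearssm_cli()' fit --data data --model 1 --out fit --seed 42
Rscript -e 'wearssm::wearssm_cli()' metrics --report fit/report.json
```

## Package layout

- `R/` — domain types and IO (`sensor_series`, `meal_log`,
  `read_participant`), preprocessing (`gp_detrend`, `sd_normalize`,
  `rmssd_inverse`), the state-space engine (`discretize`,
  `kalman_filter`, `simulate_path`), the three models, inference
  (`map_estimate`, `hmc_sample`, `bic`, `explained_variance`, `rhat`),
  the synthetic generator and the CLI.
- `src/kalman.cpp` — compiled filter/smoother and a specialized fast
  glucose-model likelihood with finite-difference gradients.
- `vignettes/wearable-state-space.Rmd` — the methods account: model
  assumptions, priors, numerical choices, what the synthetic world does
  and does not establish, limitations.
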