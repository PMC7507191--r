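# tempobisect

Simulation and analysis of audio-visual **temporal bisection**
experiments, built for studying how children — typically developing and
dyslexic — combine auditory and visual timing cues.

In a bisection trial three brief events span one second (anchors at 0
and 1000 ms, a probe in between) and the observer reports whether the
probe seemed closer in time to the first or the third event. Fitting a
cumulative Gaussian to the "closer to third" responses yields the point
of subjective equality (PSE, the curve's mean — expected near 500 ms
when unbiased) and the discrimination threshold (σ, its SD). Bimodal
trials can carry an audio-visual conflict Δ ∈ {−50, 0, +50} ms applied
with opposite sign at the probe versus the anchors (net relative
conflict ±100 ms), which exposes the weight each modality receives.

The core model is maximum-likelihood (optimal) cue combination:

    w_V = σ_A² / (σ_A² + σ_V²),   w_A = 1 − w_V
    σ_VA² = σ_V² σ_A² / (σ_V² + σ_A²)  ≤  min(σ_V², σ_A²)
    predicted conflict PSE shift = Δ (w_V − w_A)

An observer integrating optimally gains bimodal precision (σ_VA below
both unisensory thresholds, at best by √2) and shifts little under
conflict when weights are balanced; an auditory-dominant observer gains
nothing and shifts by −Δ. The package provides:

* **stimulus design** — trial/session construction with the conflict
  geometry (`build_trial`, `build_session`);
* **synthetic observers** — parameterised noise, bias, lapse, and
  integration mode, plus stock "typical" and "dyslexic" cohorts
  (`observer_params`, `sample_cohort`);
* **QUEST adaptive placement** — per-condition Bayesian posterior over
  the PSE with perturbed-mode placement and ~20% easy trials
  (`run_quest_session`);
* **psychometric fitting** — Bernoulli-ML cumulative Gaussian with
  bootstrap SEs and a grid-search reference (`fit_cumulative_gaussian`,
  `bootstrap_se`);
* **cue-combination predictions** — per-subject weights, σ_VA, and
  normalized conflict shifts (`mle_prediction`, `predict_subjects`);
* **cohort analysis** — pooled bimodal thresholds, paired
  observed-vs-predicted tests, correlations with clinical covariates
  (bootstrap CI + permutation p), Fisher z comparison of correlations,
  and a packaged 32-subject clinical table (`group_report`,
  `load_table1`, `compare_correlations`).

## Worked example

Simulate an auditory-dominant observer (σ_A = 100 ms, σ_V = 200 ms),
run one 150-trial adaptive session, fit every condition, and compare
the bimodal data with the optimal-integration prediction:

```r
library(tempobisect)
obs  <- observer_params(sigma_A = 100, sigma_V = 200, mode = "AUDIO_DOMINANT")
log  <- run_quest_session(obs, seed = 1)
fits <- fit_conditions(log, lapse = 0.02, n_boot = 100, seed = 2)
fits
#>   condition pse_ms sigma_ms se_pse_ms se_sigma_ms n_trials converged
#> 1         V    533    174.9      60.0        89.4       30      TRUE
#> 2         A    476     58.1      57.6       137.5       30      TRUE
#> 3    AV_neg    587     92.8      47.7        41.8       30      TRUE
#> 4   AV_zero    514     94.3      30.7        37.5       30      TRUE
#> 5    AV_pos    407     93.1      31.4        39.4       30      TRUE

pooled_bimodal_fit(log, n_boot = 100, seed = 3)
#> <psychometric_estimate> [AV_pooled] PSE = 499.0 ms (SE 26.8), sigma = 147.1 ms (SE 30.1), n = 90

mle_prediction(sigma_V = fits$sigma_ms[fits$condition == "V"],
               sigma_A = fits$sigma_ms[fits$condition == "A"])
#> <mle_prediction> w_V = 0.099, w_A = 0.901, sigma_VA = 55.1 ms; shifts (-50/0/+50): 40.1/0.0/-40.1 ms
```

Reading the output: the unisensory fits put most of the weight on
audition (w_A ≈ 0.90), so optimal integration would predict a pooled
bimodal threshold near 55 ms — but this observer is auditory-dominant
by construction and its observed pooled threshold (147 ± 30 ms) shows
no such gain, the signature the cohort analysis tests at group level.
The conflict PSEs (587/514/407 ms across Δ = −50/0/+50) shift by
roughly −Δ, as audio dominance predicts.

The numbered scripts under `analysis/` run the full synthetic study —
`01_simulate_cohorts.R` (two 32-subject cohorts, adaptive sessions),
`02_fit_psychometric.R` (384 fits with 100 bootstrap iterations each),
`03_model_predictions.R`, `04_cohort_report.R` — writing summary tables
to `results/`. `run_study()` does the same in one call from one seed.

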