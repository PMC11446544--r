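# cardiorivalry

Cardiac-phase-locked stimulation and analysis for binocular rivalry
experiments.

Sensory signals from the heart reach the brain in a pulsed rhythm:
arterial baroreceptors fire during **systole** (between the ECG R-peak
and the T-wave offset) and fall silent during **diastole**. Experiments
probing how this rhythm shapes visual awareness entrain visual stimuli
to a subject's ECG in real time — one stimulus pulsing in systole, one
in diastole — and measure how long each stimulus dominates in binocular
rivalry, alongside a heartbeat-discrimination task that asks whether
the subject can consciously tell which stimulus follows their heart.

`cardiorivalry` implements the complete computational pipeline of such
a study for experimenters and methodologists:

* **Streaming ECG processing** — a sample-causal Pan-Tompkins R-peak
  detector (5–15 Hz bandpass, derivative, squaring, 150 ms integration,
  adaptive thresholds, 200 ms refractory, search-back) whose chunked
  and batch runs are bit-identical, plus offline 0.5 Hz baseline
  removal and T-wave-offset delineation with a stated accuracy
  contract.
* **Pulse scheduling** — in-phase pulses commanded
  `target - adc_latency` after each R-peak (175 ms commanded / 210 ms
  on screen at the defaults) so they peak at maximal baroreceptor
  firing despite acquisition latency; anti-phase pulses delayed by half
  the preceding R–R interval; Gaussian amplitude traces at update
  (100 Hz) and render (60 Hz) rates.
* **Cardiac angles** — event times mapped to the circle (R-peak at
  ±π, T-wave offset at 0; systole negative, diastole positive), with
  subject-level circular bootstrap CIs and a hierarchical
  (random-effects) group bootstrap; a per-subject manipulation check
  that in-phase pulses landed in systole and anti-phase pulses in
  diastole.
* **Dominance-duration inference** — the marginal gamma model
  `log E[duration] = b0 + b1 · systole` fit by GEE with subject
  clusters, exchangeable working correlation and a bias-reduced
  sandwich covariance; `100·(exp(b1) − 1)` is the percent change in
  mean dominance for systole-entrained stimuli. A subject-level paired
  bootstrap (BCa) gives the estimation-statistics view, and
  `paired_t_power()` the noncentral-t power calculation.
* **Heartbeat-discrimination mixture** — each subject's correct count
  is at-chance `Binomial(n, 0.5)` or above-chance `Binomial(n, p)` with
  `p = 0.5 + Beta(α, β)/2`; priors `α ~ Exp(1)`, `β ~ Exp(0.5)`,
  prevalence `~ Uniform(0, 1)`. A deterministic gridded posterior
  yields prevalence and accuracy summaries (means, 95% HDIs),
  per-subject membership probabilities by Bayes' rule, an at-chance
  screen at 95% posterior probability, and the one-sided exact binomial
  comparison.
* **Synthetic cohorts** — generators for autocorrelated R–R series,
  delineatable ECG waveforms with exact ground-truth events,
  gamma-distributed rivalry sessions with a multiplicative systole
  effect and subject heterogeneity, and discrimination outcomes from
  the two-component mixture; BIDS-like TSV/JSON/YAML input and output.

## Worked example

Simulate a 54-subject cohort at the default study conditions (two
10-minute rivalry blocks; a +2.64% multiplicative systole effect on
mean dominance duration) and analyze it:

```r
library(cardiorivalry)

cfg <- cohort_config()
dom <- simulate_rivalry_cohort(cfg, seed = 11)

paired_bootstrap(dom, n_boot = 10000, seed = 11)
#> <paired_estimate> systole - diastole: 0.071 s, 95% CI [0.039, 0.107] (10000 boots)
#>   left eye: 0.075 s [0.022, 0.139]
#>   right eye: 0.070 s [0.026, 0.115]

fit_gamma_gee(dom)
#> <gee_result> gamma GEE (log link, exchangeable working correlation)
#>   systole beta = 0.0258 (robust SE 0.0052), t = 5.013, p = 0.0000
#>   95% CI [0.0155, 0.0362]; percent change 2.62% [1.56, 3.69]
#>   26783 intervals, 54 subjects, dispersion 0.329, rho 0.336
```

The paired estimate says systole-entrained gratings dominated 0.071 s
longer on average; the GEE coefficient (0.0258 on the log scale, i.e. a
2.62% increase) recovers the generative effect `log(1.0264) = 0.026`.

The real-time chain, closed loop — simulate an ECG, detect R-peaks in
streaming mode, schedule pulses, delineate T-waves and check where the
pulses landed:

```r
rp  <- simulate_rr_series(mean_rr = 0.8, rr_sd = 0.05, duration = 120, seed = 42)
rec <- simulate_ecg(rp, fs = 100, noise_sd = 0.05, seed = 43)
detect_rpeaks(rec, streaming = TRUE)
#> <rpeak_train> 151 peaks, mean R-R 0.798 s

ang <- subject_pulse_angles(rec)   # replay + delineation + angle map
subject_bootstrap(ang$angle[ang$stimulus == "inphase"], n_boot = 10000, seed = 1)
#> <circular_summary> mean -1.378 rad, 95% CI [-1.403, -1.353] (n = 150, 10000 boots)
```

The in-phase pulses peak at a mean cardiac angle of −1.38 rad — inside
systole (negative half of the cycle), as commanded.

Heartbeat discrimination, on a cohort with a well-separated
above-chance population (prevalence 0.25, accuracy `0.5 + Beta(8, 4)/2`):

```r
disc <- simulate_discrimination(cohort_config(prevalence = 0.25, alpha = 8, beta = 4),
                                seed = 20)
fit <- fit_mixture(disc[, c("subject", "k", "n")], seed = 20)
fit
#> <mixture_posterior> 54 subjects x 120 trials
#>   prevalence of above-chance perceivers: 0.292 (95% HDI [0.118, 0.500])
#>   mean above-chance accuracy: 0.755 (95% HDI [0.630, 0.862])

scr <- screen_at_chance(disc, fit)
length(scr$retained); scr$cutoff
#> [1] 16
#> [1] 0.475
```

Sixteen subjects clear the 95%-posterior at-chance screen (effective
accuracy cutoff 0.475). At small cohort sizes the mixture can be only
weakly identified — prevalence trades off against an accuracy law
spiked at 0.5 — in which case the screen legitimately retains nobody;
the methods vignette (`vignettes/cardiac-rivalry-methods.Rmd`)
discusses this regime, every model assumption, and all numerical
choices.

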