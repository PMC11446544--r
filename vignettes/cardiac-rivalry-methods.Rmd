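---
title: "Methods: cardiac-phase-locked stimulation and its analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiac-phase-locked stimulation and its analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiorivalry)
```

`cardiorivalry` implements the computational pipeline of a class of
experiments that entrain visual stimuli to the cardiac cycle and ask how
cardiac phase shapes visual competition. This vignette is the package's
account of the underlying models, the parameters that matter, the design
choices that were genuinely open, and what the synthetic-data tests do
and do not establish about real recordings.

## The experimental model

A subject views two rivalrous gratings, one per eye. Both gratings
"pulse" (briefly widen) with a Gaussian amplitude profile; one pulse per
heartbeat is locked to cardiac **systole** (the interval from the ECG
R-peak to the T-wave offset, when arterial baroreceptors fire) and a
second to **diastole** (T-wave offset to the next R-peak, when they are
silent). The subject reports perceptual switches, yielding dominance
intervals labelled by the entrained phase. A separate two-alternative
task (which of two pulsing circles follows the heart?) measures whether
the subject can consciously detect the entrainment, over 120 ten-second
trials.

Four computational problems follow, each a package module:

1. detect R-peaks from a low-rate (100 Hz) single-channel ECG *in a
   streaming fashion*, so pulses can be scheduled in real time
   (`detect_rpeaks()`, `rpeak_detector()`);
2. schedule pulse peaks relative to each R-peak, compensating the
   acquisition latency, and verify post hoc where in the cardiac cycle
   the pulses actually landed (`schedule_inphase()`,
   `schedule_antiphase()`, `cardiac_angle()`, `manipulation_check()`);
3. estimate the effect of systole entrainment on dominance durations
   (`paired_bootstrap()`, `fit_gamma_gee()`);
4. decide which subjects are above chance at heartbeat discrimination
   without interpreting frequentist null results (`fit_mixture()`,
   `screen_at_chance()`).

## Real-time chain

### R-peak detection

`detect_rpeaks()` is a Pan-Tompkins detector: causal 5–15 Hz
second-order Butterworth bandpass, five-point derivative, squaring, and
150 ms moving-window integration, followed by adaptive signal/noise
thresholds on the local maxima of the integrated signal. The constants
are the canonical ones: threshold updates `0.125/0.875`, a 200 ms
refractory period, search-back when no beat is accepted within 1.66
times the running R–R average (with the `0.25/0.75` update), thresholds
initialized from the first two seconds. Each accepted integrator peak is
mapped back to the R-peak by the largest absolute deflection of the raw
signal in a 0.25 s look-back window, which also cancels the causal
filter delay and makes detection invariant to amplitude scale and
polarity.

Every decision uses only past samples. The detector object carries exact
filter and threshold state between calls, so feeding the signal in
chunks of any size reproduces the batch result bit for bit — the
streaming/batch equivalence the tests assert is structural, and the
filters themselves are unit-tested against `signal::filter`.

### Scheduling and latency

The acquisition chain has a known analog-to-digital latency
(`adc_latency`, default 35 ms). To make a pulse *appear* to peak at the
target time (`target_display_peak`, default 210 ms post-R, near peak
systolic pressure), it is commanded `adc_latency` early — 175 ms post-R
at the defaults. Both time stamps are kept: downstream angle analyses
use display truth, mirroring the latency-aware design of the original
system. The anti-phase pulse for beat *i* trails the in-phase pulse by
half of the *previous* R–R interval; "previous" is resolved as the
interval ending at beat *i*, so the first beat emits no anti-phase
pulse. Pulse amplitudes are unit Gaussians with scale `1/16` s; when
pulses overlap at short R–R they sum additively (no combination rule is
physically singled out, and summation keeps the trace linear in the
peaks). Traces are evaluated on a 100 Hz update grid with Gaussian tails
truncated at eight standard deviations (relative error `< 1e-13`), and a
60 Hz render trace samples-and-holds the latest update value.

### Offline delineation and cardiac angles

Offline, the signal is high-passed at 0.5 Hz (zero-phase) and T-wave
offsets are delineated per beat: the T extremum is sought in
`(R + 150 ms, R + 60% of R–R)`, and the offset is the first sample after
the extremum to fall below 10% of the T amplitude. Amplitude is measured
against a local diastolic baseline (median of the 100 ms before the next
R), because the high-pass leaves a small undershoot after the T-wave
that would otherwise bias the crossing early by ~30 ms. This
threshold-on-the-descending-limb rule is deliberately simple; it is
*not* a re-implementation of any published wavelet delineator, and its
accuracy contract (mean absolute error ≤ 30 ms against synthetic ground
truth; measured ~7 ms noiseless, ~15 ms at the default noise level) is
enforced by tests.

Event times map to **cardiac angles**: within each beat, systole is
scaled linearly onto `(-pi, 0)` (R-peak at `-pi`, T-offset at 0) and
diastole onto `(0, pi)` (next R-peak at `pi`). An event exactly at an
R-peak is assigned the systole-start convention `-pi` (the same circle
point as `+pi`); events in beats lacking a T-offset are dropped and
counted. Per-subject mean angles use the circular mean (direction of the
mean resultant vector) with a percentile bootstrap CI computed on
replicate deviations from the point estimate — unwrapped to
`(-pi, pi]` so means near the R-peak branch cut get contiguous
intervals. The group level uses a hierarchical (random-effects)
bootstrap: resample subjects, then each chosen subject's angles, then
take the group circular mean of subject circular means. Subjects are
canonicalized by sorted name and given independent seed substreams, so
results are invariant to input order. The manipulation check passes only
if every complete subject has a negative in-phase mean angle and a
positive anti-phase mean angle.

## Dominance-duration analyses

Rivalry dominance durations are approximately gamma. The package fits
the marginal model `log E[duration] = b0 + b1 * systole` by generalized
estimating equations with gamma variance, subjects as clusters, and an
exchangeable working correlation (`independence` available). The log
link is used because the effect of interest is naturally multiplicative
— `(exp(b1) - 1) * 100` is the percent change in mean dominance for
systole-entrained stimuli — and a working correlation stands in for
subject-level random effects without parametric commitment.

Inference uses a robust sandwich covariance. Two small-sample choices
matter at the cohort sizes this model targets (tens of subjects):

* the default covariance is the **Mancl–DeRouen bias-reduced sandwich**
  (per-cluster residuals inflated by `(I - H_i)^-1`, computed via the
  Woodbury identity so only 2×2 algebra is needed per cluster). In
  simulation at 54 subjects the plain Liang–Zeger estimator understates
  the SE of `b1` by roughly 10%, pushing Wald coverage to ~92%;
* p-values and CIs use a **t reference with `clusters - 2` degrees of
  freedom** rather than the normal, which is known to be liberal with
  few clusters.

With both, measured CI coverage at the default study conditions is
~93–94% and type-I error ~6–8% — closer to nominal but still slightly
liberal, which appears intrinsic to sandwich inference in this design
(large clusters, a purely within-cluster contrast, working correlation
~0.3). `cov_type = "robust"` restores the uncorrected Liang–Zeger
covariance for exact comparison with analyses that use it (the
independence special case is test-verified to equal `glm`'s gamma fit,
and both covariance types are verified to machine precision against an
independent GEE implementation).

The estimation-statistics companion, `paired_bootstrap()`, resamples
subjects with replacement and reports the mean systole-minus-diastole
difference of subject-level mean durations with a BCa interval
(`boot::boot.ci`; percentile optional), overall and stratified by eye.
Block-truncated final intervals are flagged `censored` by the generator
and excluded from all analyses by default — boundary intervals are not
full dominance episodes, and no principled completion exists for them.

`paired_t_power()` computes paired t-test power from the noncentral t
distribution (df `n - 1`, noncentrality `d * sqrt(n)`); at the planning
effect size `d = 0.38` it reproduces 0.81 for 58 pairs and 0.78 for 54.

## The discrimination mixture

Subject *i*'s correct count is modelled as
`k_i ~ Binomial(120, 0.5)` (at-chance) or
`k_i ~ Binomial(120, p_i)` with `p_i = 0.5 + B/2`, `B ~ Beta(alpha,
beta)` (above-chance), with population prevalence `pi_pop` of
above-chance perceivers. Priors: `alpha ~ Exp(1)`, `beta ~ Exp(0.5)`
(mildly favouring accuracies near 0.5), `pi_pop ~ Uniform(0, 1)`. Note
the above-chance component is a *shifted*-Beta mixture on `[0.5, 1]`,
not a standard Beta-Binomial.

`above_chance_likelihood()` evaluates the marginal
`P(k | above-chance)` by a fixed 256-node tanh-sinh (double-exponential)
quadrature on `(0, 1)`. A Gauss–Legendre rule was rejected: whenever a
shape parameter is below 1 — most of the prior mass — the Beta density
has an integrable endpoint singularity and a 256-node Gauss rule loses
up to `1e-3` of probability mass, while the double-exponential
substitution (with node positions and weights carried in log form so
endpoint nodes neither round to 0/1 nor overflow) keeps normalization
error below `2e-7` across the prior support and at machine precision for
shapes ≥ 0.15. The rule is tested against an exact closed form
(`alpha = beta = 1`) and a `1e6`-draw Monte-Carlo oracle.

`fit_mixture()` computes the joint posterior on a deterministic product
grid — 96 uniform prevalence cells and 64 equal-prior-mass cells for
each shape parameter — under the marginalized likelihood (no per-subject
latent labels), then draws 10,000 parameter triples by sampling cells by
posterior weight and jittering uniformly in prior mass within the cell.
A three-parameter smooth posterior does not need MCMC; the gridded
posterior is exactly reproducible, which the tests and the calibration
studies exploit. Its calibration is established two ways: 95% HDI
coverage of a known prevalence across replicate cohorts, and
simulation-based calibration (uniformity of the true parameter's rank
among posterior draws when cohorts are generated from the prior). On a
fixed dataset the gridded posterior was also checked against an
independent MCMC sampler driven by an exact finite-sum likelihood; means
and intervals agree. Instead of MCMC convergence diagnostics, the fit
flags posterior mass piling onto the outermost shape cells (more than
three times their prior mass), the failure mode a grid actually has.

Membership follows by Bayes' rule, averaged over the posterior:
`P(above | k) = E[ pi L_a(k) / (pi L_a(k) + (1 - pi) L_c(k)) ]`.
`screen_at_chance()` retains subjects with membership at most 0.05 —
at least 95% posterior probability of being at-chance — and reports the
effective accuracy cutoff (largest retained `k/n`). The one-sided exact
binomial flag (`binomial_above_chance()`) is computed alongside so the
divergence between the frequentist cutoff and the posterior screen is
visible on any cohort.

One behaviour worth knowing: with 54 subjects the mixture is only
weakly identified when the realized cohort happens to lack clear
above-chance performers. The posterior then spreads onto a
small-`alpha` / high-prevalence ridge (many "above-chance" subjects
indistinguishable from chance), every membership probability rises
above the screening threshold, and the screen retains nobody. This is a
property of the model, verified against the independent sampler, not an
estimation artifact; downstream consumers (e.g. the acceptance script)
treat the screen-dependent quantities as undefined in that case.

## The synthetic-data generator

The generator defines the conditions under which every stage is tested;
its defaults were fixed once, as follows:

* **Rhythm** — subject mean R–R intervals are normal (mean 0.8 s, SD
  0.07 s) truncated to 0.6–1.0 s (60–100 bpm); within a subject, R–R
  intervals follow a stationary AR(1) Gaussian process (marginal SD
  0.05 s, lag-1 correlation 0.3, floored at 0.3 s) — the simplest law
  with the autocorrelated variability sinus rhythm shows.
* **ECG** — a beat-template sum: unit Gaussian QRS (sigma 15 ms,
  rate-independent) plus a T-wave Gaussian scaled to the beat (center
  at 31.25% of R–R, sigma 7.5% of R–R, amplitude 0.3), so the
  ground-truth T-offset (center + 2 sigma = 46.25% of R–R) is exact by
  construction and always lies strictly inside the beat; at the default
  0.8 s R–R these are 250 ms, 60 ms and 370 ms post-R. White noise, SD
  5% of QRS amplitude by default. Fractional (rather than absolute)
  T-wave timing was chosen so fast rhythms cannot push the T-offset
  past the next R-peak.
* **Rivalry** — two 10-minute blocks of alternating gamma intervals
  (shape 4, baseline mean 2.5 s — typical rivalry values), the systole
  condition's mean multiplied by `1 + systole_effect` (default 0.0264,
  i.e. a log-effect of 0.026), a log-normal subject effect (log-SD
  0.3) multiplying both conditions, eye/condition mapping swapped
  between blocks, final interval truncated at the block boundary and
  flagged censored.
* **Discrimination** — 120 trials; above-chance subjects drawn with
  prevalence 0.0948 and accuracies `0.5 + Beta(2, 4)/2` (mean 0.667),
  mirroring the estimates this design reports; latent labels are
  returned as ground truth.

What the generator does *not* emulate: realistic multi-lead ECG
morphology, arrhythmias and ectopic beats, electrode artifacts and
baseline wander beyond white noise, piecemeal/mixed rivalry percepts,
response-time jitter in switch reports, and any coupling between
interoceptive ability and the rivalry effect (the two tasks are
simulated independently). Passing closed-loop tests therefore establish
that the chain is internally correct under clean, well-specified
physiology — not that detection or delineation would reach the same
accuracy on noisy clinical recordings.

## Numerical choices and degenerate inputs

* Fixed seeds make every generator and bootstrap bit-reproducible; root
  seeds spawn deterministic per-subject substreams
  (order-invariance).
* Filters: zero-phase (`filtfilt`) offline, causal stateful filters in
  the streaming path.
* GEE Fisher scoring iterates to `max |delta beta| < 1e-10` (50
  iterations cap) and errors with diagnostics on non-convergence; the
  working correlation is clamped to `[0, 0.95]`.
* Zero-resultant circular means raise an error rather than returning an
  arbitrary direction; zero-spread bootstraps return zero-width CIs.
* Flat ECG signals yield an empty peak train with a warning; recordings
  shorter than 2 s, bands outside Nyquist, non-positive durations and
  invalid mixture parameters are rejected up front.
* The detector's first two seconds initialize thresholds; beats in that
  window are recovered retroactively, and accuracy contracts in the
  tests exclude nothing else.

## Problem sizes used by the test suite

Simulation-backed checks are sized to establish their property with
conventional Monte-Carlo error while staying desk-scale: 200 cohorts
(plus 400 null cohorts) for GEE coverage and type-I calibration, 100
cohorts for mixture HDI coverage, 32 prior-drawn cohorts for
simulation-based calibration, 300 von Mises samples for circular
bootstrap coverage, 200 simulations for paired-bootstrap coverage, and
20 simulated subjects with 10-minute recordings for the closed-loop
manipulation check. The corresponding acceptance bands are binomial
bands around the nominal rates at those replicate counts.

## Known limitations

* The T-offset delineator is a stated-accuracy surrogate, not a
  re-implementation of wavelet delineation; systematic offsets of a few
  ms relative to other delineators are expected.
* Sandwich-based GEE inference remains ~1–2 pp liberal at 54 clusters
  even after bias reduction and the t reference.
* The gridded posterior is exact only up to its grid; extremely
  concentrated posteriors (e.g. hundreds of subjects) would need more
  prevalence cells than the default 96.
* The mixture's weak-identifiability regime (above) makes the at-chance
  screen conservative to the point of emptiness on some small cohorts.
* Streaming detection emits a peak only after the integrator maximum is
  confirmed (~150–250 ms after the R-peak); the scheduler relies on the
  pulse target being later than that plus processing margin, which
  holds at the default 210 ms target only because commanded times may
  be realized late by the renderer's sample-and-hold. Real deployments
  should measure their end-to-end latency as the original system did.
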