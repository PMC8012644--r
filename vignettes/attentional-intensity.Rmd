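---
title: "Models and methods: single-trial analysis of attentional intensity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: single-trial analysis of attentional intensity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(v4intensity)
```

# Overview

This package implements a single-trial analysis chain for experiments in
which the *intensity* of attention — overall engagement, as opposed to its
spatial selectivity — is manipulated by alternating reward size over blocks
of trials. It couples a synthetic session generator with known ground truth
to estimators for behavior, pupil physiology, spike statistics,
receptive-field geometry, negative-binomial encoding models, and population
decoding. Because the generator's parameters are all recoverable, every
estimator ships with calibration tests against its own generative truth.

# The behavioral observer

Behavior is an equal-variance Gaussian signal-detection observer.
Sensitivity and criterion are estimated from hit rates on nonmatch
(orientation-change) trials and false-alarm rates on match trials:

$$d' = \Phi^{-1}(\text{hit}) - \Phi^{-1}(\text{FA}), \qquad
c = -\tfrac12\left[\Phi^{-1}(\text{hit}) + \Phi^{-1}(\text{FA})\right].$$

Overall (spatially nonselective) sensitivity combines the two hemifields as
$d'_{\text{overall}} = (d'^2_{\text{InRF}} + d'^2_{\text{OutRF}})^{1/2}$.
The generator inverts these identities: on each trial the probability of a
saccade is $\Phi(d'(t)/2 - c)$ on nonmatch trials and $\Phi(-d'(t)/2 - c)$
on match trials, where the instantaneous $d'(t)$ relaxes toward the block
asymptote with a direction-dependent exponential trial constant. Defaults
are $d'$ asymptotes 2.03 (small reward) and 3.48 (large), criterion 0,
rise constant 12.2 trials and decay constant 1 trial — a slow engagement of
intensity after reward increases and a fast disengagement after decreases,
which is what produces hysteresis in reward–response trajectories.

Two numerical conventions matter here. Rates of exactly 0 or 1 are clipped
to $1/(2N)$ and $1 - 1/(2N)$ of their class before the probit transform
(the log-linear correction); the identities round-trip to machine precision
away from clipping. And trial-course $d'$ at aligned order $i$ pools all
responses at that order across blocks; when a session has only a few blocks
per condition, `aligned_dprime(bin_width = ...)` pools adjacent orders so
rates are defined (the pipeline uses a width of 5 for sessions under 20
blocks; with many blocks the width is 1).

# Pupil area

Raw binocular traces are normalized per session and per eye by the extrema
over the 0–400 ms window after sample onset, then averaged across eyes;
mean pupil area is the 0–400 ms average of that trace. The generator's
pupil state relaxes toward a condition level (defaults 0.40 small, 0.62
large, in normalized units) with rise constant 4 and decay constant 9
trials, carries trial-to-trial Gaussian noise (SD 0.04), and adds a
stimulus-evoked alpha-function transient (amplitude 0.15, peak 250 ms).
Raw per-eye traces are produced by distinct affine maps into device units
plus sensor noise, so the normalization path is exercised end to end.
Importantly, spike counts are generated *after* normalization, using the
same per-trial mean pupil area the analysis reconstructs — fitted pupil
coefficients are therefore directly comparable to their generative values.

Pupil–spike coupling is measured three ways: ordinary least squares of
z-scored pupil area on z-scored spike counts and an intensity label
(fitted without an intercept, which the z-scoring makes well-posed; the
intercept-free form keeps coefficients comparable across neurons); a
shuffle-corrected cross-correlation between 10-ms-binned spike rates
(2 ms steps) and the 500 Hz pupil trace; and a shuffle-corrected
spike-triggered pupil average. The shuffle terms pair spikes with pupil
traces from other trials, which removes stimulus-locked common structure;
under trial-exchangeable independence the corrected measures have zero
expectation, and undefined lags (zero-variance series) are reported as
missing, never as zero. The reduced pupil-on-spikes regression is fit per
reward condition on trial subsets matched on pupil area by greedy
nearest-neighbor pairing with a 0.05 caliper (normalized units) — the
matching procedure is a package choice, made explicit in the configuration.

# Spike statistics

Units enter analysis if their evoked rate (60–260 ms after sample onset)
exceeds the −250–0 ms baseline in a one-sided paired test at p < 0.01.
PSTHs bin spikes at 2 ms and smooth with a causal half-Gaussian kernel
(SD 15 ms, rightward tail only, unit mass), so no response mass leaks
before its cause. Neuronal modulation ("neuronal d′") is the difference of
mean z-scored counts between large- and small-reward blocks on correct
trials, z-scored over the unit's pooled trials.

The mean-matched Fano factor controls for firing-rate differences between
conditions: per-unit means and variances of 50 ms sliding-window counts
(2 ms steps) are histogrammed, the greatest common mean distribution across
all condition × time groups is taken bin-wise, each group is randomly
subsampled to that common histogram (20 seeded draws), and the average
variance-to-mean ratio of retained points is reported. The histogram bin
width (default 0.05 counts, i.e. 1 spike/s in a 50 ms window; coarser for
small populations) is a package constant the user can change. Calibration:
Poisson ensembles give 1.00, and NB ensembles give $1 + \mu/\theta$, within
the tolerances the test suite asserts.

Noise correlations are Pearson correlations of sample-window counts per
simultaneous pair and reward condition, binned by the geometric mean of the
pair's evoked rates (5 Hz bins, top bin pooling everything above 25 Hz;
evoked = 60–260 ms rate minus the −200–0 ms baseline). Baseline windows
deliberately differ across analyses (−250–0 for screening, −200–0 for
evoked responses) and are separate constants, not unified. Pairs with a
zero-variance member are skipped and counted, so denominators are
auditable.

Reward-history dependence is probed without the GLM by sorting trials into
nine overlapping bins (width 0.2, stride 0.1) of the previous completed
trial's session-normalized reward and averaging mean-normalized counts on
the following trial, separately for early (aligned trials 1–10) and late
(61–120) block phases.

# Receptive-field geometry

Spatial RFs are bivariate Gaussians fit by nonlinear least squares
(amplitude × Gaussian + baseline, moment-based initialization). The
proximity of an RF to the stimulus is the overlap of their unit-mass
densities; the package uses the overlap coefficient
$100\int \min(f, g)\,dA$ on a grid covering ±4 SD of both densities at
resolution min(σ)/20, with the Bhattacharyya coefficient available as an
alternative since the choice of overlap integral is genuinely open. For
equal isotropic Gaussians the overlap coefficient has the closed form
$2\Phi(-d/2\sigma)$, which the tests use as an oracle. A spatially
*nonselective* intensity signal predicts no correlation between a unit's
modulation and its RF–stimulus overlap; `overlap_vs_modulation()` reports
the Spearman correlation and means over four equal overlap intervals with a
one-way ANOVA. The generator can couple the intensity gain to overlap
(`intensity_coupling = "overlap"`) to verify the analysis detects the
selective alternative.

# The negative-binomial encoding model

Counts in the 60–260 ms window are modeled as
$y \sim \mathrm{NB}(\mu, \theta)$ with $\mu = \exp(X\beta)$ and
$\mathrm{Var}(y) = \mu + \mu^2/\theta$; in the success-probability
parameterization this is $\mu = \theta p/(1-p)$, and $\theta \to \infty$
is the Poisson limit. The sample-period complete model uses a 0/1 sample
orientation indicator, mean pupil area, the saccade indicator, and ten
reward-history lags (reward $k$ completed trials back, normalized within
session; trials lacking a full history are dropped and counted). Test-period
models replace orientation with a stimulus feature — the unit's orientation
tuning filter (mean-normalized training-set response per test orientation)
indexed by the trial's test orientation — and swap the saccade indicator
for the orientation-change indicator; only trials with the test stimulus
inside the recorded RFs are used. The tuning filter must be estimated on
training trials only; `build_design(filter_trials = ...)` enforces this in
cross-validated settings, and a test audits that held-out responses cannot
leak into the filter. Units whose stimulus-feature partial prediction rank
correlates with the orientation-change partial prediction at $|r| \ge 0.2$
are excluded from orientation-change inference.

Estimation alternates IRLS for $\beta$ at fixed $\theta$ (with
step-halving, so the log-likelihood ascends monotonically) and a
one-dimensional profile-likelihood search for $\theta$ on the log scale,
until the log-likelihood changes by less than $10^{-8}$; $\theta$ is
initialized by method of moments from Pearson residuals of a Poisson fit
and capped at $10^6$. All likelihoods are evaluated in log space via
`lgamma` — the raw pmf overflows for realistic counts. Standard errors come
from the expected information $X^\top W X$, $w = \mu/(1 + \mu/\theta)$.
The implementation reproduces an independent ML implementation
(`MASS::glm.nb`) to five decimals in the tests, and $\theta$-capped fits
match a Poisson IRLS oracle to $10^{-4}$.

Diagnostics: residual deviance uses a saturated model with the predicted
response equal to the observed response at the model's fitted $\theta$
(the saturated $\theta$ is not separately estimable); the likelihood-ratio
statistic against the intercept-only null is referred to a $\chi^2$ with
degrees of freedom equal to the number of non-intercept predictors; and the
Cragg–Uhler pseudo $R^2$,
$[1 - (L_0/L_1)^{2/n}] / [1 - L_0^{2/n}]$, is 0 for the null model and
bounded by 1. Standardized coefficients are
$\beta'_j = \beta_j \,\sigma_{x_j}/\sigma_y$ — the log-rate change, in
units of response SD, per one-SD predictor change — which makes them
invariant to predictor rescaling (the tests assert this); categorical 0/1
columns use the SD of their coding. Predictor importance is $|\beta_j /
\mathrm{SE}(\beta_j)|$. Predictive performance uses 10-fold seeded
cross-validation with mean squared error on held-out counts; pseudo $R^2$
is computed on the full data, with CV error reported separately.

# Population decoding

For each trial and each unit whose model is significant at p < 0.05, the
log-likelihood of the observed count is evaluated under both values of the
decoded variable, holding all other predictors at their observed per-trial
values (the fitted model conditions on them). With a flat prior the summed
log-likelihood ratio across units is the posterior log-odds, and the
decoded value maximizes the likelihood; an exactly zero sum is resolved by
a seeded fair coin. Accuracy is measured on random trial pairs, one per
class, drawn without replacement (min(class sizes) pairs per seeded
repetition); a pair is correct only when both members are decoded
correctly, so chance is $0.5^2 = 0.25$. Choice decoding converts decoded
saccades into hit/miss/CR/FA using the known trial type, after resampling
minority outcome classes to balance the four counts.

Two properties of this scheme deserve emphasis. First, the 0.25 chance
level is exact for an *uninformative population* — fits whose coefficient
for the decoded variable is zero — where every log-likelihood ratio
vanishes and the coin rule applies; the calibration tests construct
exactly that population. Second, a decoder built from pure noise
coefficients is *not* chance-calibrated on held-out data: the expected
log-likelihood ratio under the true distribution is a negative KL
divergence for every trial, so such a decoder collapses onto one class and
its paired accuracy falls below 0.25. This is a property of
likelihood-ratio decoders generally, not an implementation artifact;
decoding should therefore be interpreted against the uninformative-population
baseline. Held-out decoding (`newdata`) rebuilds designs on a test session
and is the recommended way to report informative accuracies.

# What the generator emulates — and what it does not

Emulated: alternating 120-completed-trial reward blocks with gamma
rewards (means 131 µl small / 522 µl large, CV 0.25, distinct hit/CR
payoffs so reward history is not collinear with block condition); aborted
trials as a condition-dependent per-trial probability with an early-block
transient on entering small-reward blocks (aborted trials carry no payload
and do not count toward the 120); exponential behavioral/pupil/rate
dynamics with direction-dependent constants; per-neuron NB-GLM spike counts
whose predictors are exactly those the analysis reconstructs; per-neuron
bivariate-Gaussian RFs scattered around the stimulus (σ ≈ 1.1°, stimulus
envelope σ = 0.5°); and, when spike times are requested, a
response-shaped evoked density carrying the NB sample-window count plus
baseline Poisson spiking (8 spikes/s).

Not emulated: millisecond-scale point-process structure (spike history,
refractoriness, oscillations), eye movements and blink artifacts,
within-trial pupil drift between the sample and test windows (one pupil
state serves both, so test-period models reuse the sample-period mean
area), inter-neuron noise correlations beyond those induced by shared
predictors, second-test-interval dynamics beyond outcome bookkeeping, and
electrode-level confounds (waveform quality, unit drift). Passing tests
therefore certify estimator calibration under the stated generative
assumptions, not robustness to these unmodeled features of real
recordings. The gamma form of the within-block reward distribution is a
modeling choice exposed in the configuration.

# Problem sizes and runtime choices

The default session (4 blocks × 120 trials, 40 neurons) mirrors the
structure of real sessions while keeping a full pipeline run to a few
seconds. Calibration analyses choose sizes where Monte-Carlo error is
comfortably below the asserted tolerances: $10^5$ trials for observer
closed forms, 100 replicates of n = 5000 for GLM recovery, 200 units × 300
trials for Fano calibration, $10^4$ pairs for the noise-correlation null,
a 40-block session (≈2400 decodable trials) for chance-level decoding, and
50 sessions for the spatial-nonselectivity signature. Each stage's
randomness is seeded from one master seed, and sessions are bit-identical
functions of (configuration, seed).

# Known limitations

The NB fit assumes one dispersion per unit across trials; θ is capped at
$10^6$, so genuinely underdispersed counts are fit at the Poisson limit
rather than modeled. Mean-matching fails (by design, with an error) when
condition mean distributions share no histogram mass — small populations
need coarser bins. The hysteresis mid-point uses the first midpoint
crossing and flags non-monotone trajectories rather than resolving them.
The exponential fit's τ confidence interval is Wald-based and can be wide
or unstable when a series is near-constant; such series are flagged
degenerate instead of fit.
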