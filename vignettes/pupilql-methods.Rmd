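---
title: "Models and methods behind pupilql"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pupilql}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pupilql` implements a complete analysis chain for pupil size recordings
collected during probabilistic reinforcement learning: behavioral
simulation, hierarchical Bayesian model fitting, pupillometric
preprocessing, event-related deconvolution with single-trial model-based
covariates, and group-level inference. This vignette explains each model,
its assumptions, the tunable parameters, and the design decisions taken
where more than one defensible choice existed. No empirical claim is made
here that the package's tests and acceptance checks do not themselves
compute.

## The task and the behavioral model

The probabilistic selection task presents three fixed option pairs (AB,
CD, EF) whose higher-valued members are rewarded with probability 0.8,
0.7, and 0.6 respectively (the lower member with the complement). A
learning phase of 6 runs x 60 trials (120 presentations per pair) is
followed by a transfer phase of 5 runs x 60 trials pairing all 15
combinations of the six options (20 presentations each) without feedback.

Choices are modeled with Q-learning using separate learning rates for
rewarded and unrewarded outcomes. Every option value starts at 0.5. After
a choice of option $i$ with outcome $r \in \{0,1\}$:

$$Q_i \leftarrow Q_i + \begin{cases}
  \alpha_{Gain}\,(r - Q_i) & r = 1\\
  \alpha_{Loss}\,(r - Q_i) & r = 0
\end{cases}$$

with $\alpha_{Gain}, \alpha_{Loss} \in [0,1]$. Only the chosen option is
updated. The probability of choosing option $A$ over $B$ is a softmax
with inverse temperature $\beta \in [0, 100]$:

$$P(A) = \frac{e^{\beta Q_A}}{e^{\beta Q_A} + e^{\beta Q_B}},$$

computed with max-subtraction because $e^{100}$ overflows naively.
Single-trial covariates are always *pre-update* quantities: $Q_{chosen}$
and $Q_{unchosen}$ are the beliefs that drove the choice, and the reward
prediction error is $r - Q_{chosen}$. Transfer-phase values are frozen at
their end-of-learning estimates and looked up per trial; nothing updates
without feedback.

Trials with response times outside [0.15 s, 3.5 s] are excluded from the
likelihood, but their outcomes still drive the value update: the agent
experienced the feedback even when the response was too fast or too slow
to model. This is one of the genuinely open choices (the alternative is
to skip the update as well); it matters little in practice because such
trials are rare, and the choice is flagged here for sensitivity testing.

Simulated response times are log-normal (median 0.8 s, log-SD 0.3),
truncated to the admissible window — a standard positively skewed RT
shape; nothing downstream depends on its exact form beyond the boxcar
regressor needing realistic durations. Pair order is shuffled within each
run from an exactly balanced list, which guarantees the printed per-pair
counts; the alternative (fully random across the session) matches the
counts only in expectation. Option offset times are jittered (uniform
0.3–0.9 s after feedback, 0.1–0.5 s after a transfer choice): with a
constant delay the offset's FIR regressor would be an exact column-shift
duplicate of the feedback regressor and the design matrix would lose
rank. Real experiments always carry such jitter implicitly.

## Hierarchical Bayesian estimation

Subject-level parameters are estimated jointly under a two-level model.
Each parameter is probit-transformed: $\alpha = \Phi(z')$,
$\beta = 100\,\Phi(z')$, and the transformed $z'_i$ of subject $i$ is
drawn from a group-level normal with mean $\mu_{z'}$ and SD
$\delta_{z'}$. The group means receive a Normal(0, 1) prior and the group
SDs a Uniform(1, 1.5) prior. Both pairs of literals are configurable
(`hb_priors()`); the uniform support in particular is unusually
restrictive (it forbids group SDs below 1) and is kept because it is the
documented default of the modeling tradition this package follows.

Sampling uses adaptive Metropolis-within-Gibbs: a joint random-walk
proposal per subject (scale adapted toward 30% acceptance during warmup,
then frozen), an additional independence proposal drawn from the current
group distribution whose acceptance ratio reduces to the likelihood
ratio — this lets chains jump between the model's characteristic
trade-off modes (a high learning rate with moderate $\beta$ can mimic a
low learning rate with high $\beta$) — a conjugate Gibbs draw for each
group mean, and reflected random-walk steps for each group SD inside its
uniform support. Defaults are 4 chains x 1000 warmup + 1000 draws.
Convergence is summarised by split-chain Rhat for every sampled quantity;
the fit is flagged converged when all Rhat $\le 1.05$ (the tradition
reports Rhat of 1.0 but states no threshold).

Point estimates are posterior *modes*: a Gaussian kernel density
(Silverman's bandwidth) on the native-scale draws, evaluated on a
512-point grid over the sample range. Model comparison between the
two-learning-rate model and a single-rate variant uses AIC
($2k + 2\,\mathrm{nll}$) and BIC ($k\ln n + 2\,\mathrm{nll}$) with the
negative log-likelihood evaluated at the posterior-mode estimates ($k=3$
vs $k=2$ free subject-level parameters, $n$ the number of modeled
trials). Whether the original procedure plugged in modes or maximum
likelihood is unstated; modes keep a single point-estimate convention
throughout the package.

Identifiability has hard limits worth knowing: a subject with
$\beta > 85$ behaves almost deterministically (the likelihood is flat in
$\beta$ above the separation point) and a subject with a near-zero
learning rate produces near-random choices that constrain neither
$\alpha$ nor $\beta$. Under wide generating distributions a sizable
minority of simulated subjects fall in these regimes, so rank-correlation
recovery of $\beta$ is world-dependent; the package's recovery test
reports the values for its fixed simulated cohort.

## Pupil preprocessing

The preprocessing chain mirrors standard pupillometry practice: linear
interpolation across labeled blinks (from 200 ms before each blink start
to 200 ms after its end), a second pass that detects unlabeled artifacts
as samples where the first difference exceeds 6 robust SDs (median
absolute deviation, per run) and interpolates them with the same margins,
a third-order Butterworth band-pass of 0.05–4 Hz, per-run z-scoring, and
decimation to 20 Hz behind an anti-aliasing low-pass (third-order
Butterworth at 8 Hz).

Two numerical points. First, no DSP library ships with the target
environment, so the Butterworth design is implemented in the package:
prototype poles, analog band transform, bilinear mapping — kept in
factored biquad (second-order-section) form throughout because at a
0.05 Hz edge and 1000 Hz sampling the poles sit within $10^{-4}$ of the
unit circle, where expanded polynomial coefficients are numerically
useless. The design was cross-checked against an independent reference
implementation during development and its response is pinned by tests
(a 0.01 Hz sinusoid is attenuated by more than 90%, a 1 Hz sinusoid
passes within 5%). Second, filtering is applied forward and backward
(zero phase) with odd-reflection padding, and the signal is demeaned per
run first: the deconvolution stage interprets *pre-event* time, so phase
distortion would masquerade as anticipation.

Blink and saccade pupil responses are then removed by a nuisance GLM: the
event trains (blink ends, saccade onsets) are convolved with the
canonical pupil impulse response
$h(t) = (t/t_{max})^{w} e^{w(1 - t/t_{max})}$ ($w = 10.1$,
$t_{max} = 0.93$ s, unit peak), fit by least squares, and the residuals
carried forward. Anchoring blinks at their end (rather than start) is the
common convention for this kernel and is configurable. Trials containing
a saccade larger than 3.3 degrees of visual angle during the decision
interval (options onset to choice), or response times outside the
admissible window, are rejected before deconvolution.

## Deconvolution by cross-validated ridge regression

Event-related responses are estimated as finite impulse responses: each
transient regressor contributes one free coefficient per 50 ms lag of its
window (options onset and feedback: −0.5 to 3 s; choice: −2 to 1.5 s;
fixation onset and options offset as nuisance sticks at −0.5 to 3 s), a
boxcar spans each decision interval with height 1/mean(RT) so sustained
and transient coefficients are comparable, and covariate regressors
duplicate their parent event's sticks scaled by the z-scored single-trial
value ($Q_{chosen}$ and $Q_{unchosen}$ choice- and feedback-locked, the
prediction error feedback-locked). The transfer design drops all
feedback-locked regressors and adds three choice-conflict sticks from the
experimental reward-probability differences binned as 10–20%, 30–40%,
50–60%. Columns and the response are mean-centred and no intercept is
included. The matrix is held sparse and uncentered internally with a
rank-one centring correction in the normal equations; this keeps a
full-session design (50,000 samples x 700 columns) cheap.

Coefficients solve the ridge-penalised normal equations
$(X^\top X + \lambda I)\,\hat\beta = X^\top y$ by Cholesky decomposition.
The penalty is selected on a 21-point grid over $[0, 1]$ by
cross-validation with 20 contiguous hold-out blocks (random offsets, 20%
test fraction); contiguous blocks are used because pupil noise is
strongly autocorrelated and interleaved splits would leak. Prediction
accuracy is out-of-sample $R^2$; ties go to the smaller penalty. Within
each split the train-set cross-product matrix is eigendecomposed once so
all penalties cost one decomposition.

## The synthetic-data generator, and what a green test establishes

The generator emulates exactly the structure the analysis assumes: a
linear time-invariant superposition of event kernels whose amplitudes are
(base gain + effect size x z-scored covariate), a sustained boxcar, 1/f
Gaussian background noise (SD 0.5 z-units), blink artifacts (sharp signal
drops plus a slow negative recovery response), and saccades of which 5%
exceed the rejection threshold. Default effect sizes plant the pattern
the pipeline is designed to detect: +0.3 for chosen value on a pre-choice
bump (with a negative post-choice lobe, so the chosen-minus-unchosen
difference reverses sign after the choice), ±0.15 opposite-signed
chosen/unchosen slopes on the fast feedback component (value
uncertainty), and −0.3 for the prediction error on the late (~2 s)
feedback component. Transfer-phase synthesis plants *no* value
modulation, making the learning-vs-transfer dissociation testable. The
feedback response is biphasic by construction: a fast canonical IRF plus
a negative Gaussian component centred at 2 s. Kernels are numerically
compact within the estimation windows; energy beyond the estimated lags
would alias into collinear regressors and bias amplitude recovery, which
is a real concern for real data too and the reason amplitude-recovery
checks use compact kernels.

What the generator does *not* emulate: gaze-dependent foreshortening,
luminance responses, non-linear saturation of the pupil, drift in
electrode-style gain, omission trials, or any non-LTI dependence of
response amplitude on inter-event spacing. A green end-to-end test
therefore establishes that the pipeline's estimators are consistent for
the model class they assume — not that real pupils obey that class.

Because per-run z-scoring rescales the signal by the run SD, recovered
coefficients live on the standardised scale; recovery tests multiply back
by the recorded run SDs (`attr(ts, "run_stats")`) before comparing with
planted amplitudes.

## Group statistics

Per-timepoint one-sample t-tests against zero (two-tailed, cluster-forming
threshold p < .05) define clusters as runs of contiguous suprathreshold
samples scored by their *size*; the null distribution records the maximal
cluster size under random per-subject sign flips, and the corrected
p-value is $(1 + \#\{\text{null} \ge \text{obs}\})/(n_{perm}+1)$. Sign
flipping is the exact permutation scheme for a symmetric one-sample null.
A caveat documented by the package's own calibration test: on unsmoothed
iid null data the max-cluster-size statistic takes so few distinct values
at 34 subjects x 70 timepoints that the realised familywise error the
test measures sits near 0.01, well below the nominal 0.05 — conservative,
never inflated. On smooth time courses, as deconvolved responses are, the
granularity is milder.

Interval summaries divide the summed coefficients by the number of
samples (an interval mean); end-locked summaries discard post-event lags.
Across-subject inference on scalar pupil measures regresses them on the
three model parameters jointly (standardised), with 10,000 bootstrap
resamples of subjects, percentile 68% bands, and two-sided p-values as
the doubled smaller tail fraction around zero. The feedback-response
amplitude scalar is peak-to-trough: the maximum over 0.5–1.5 s minus the
minimum over 1.5–3 s post-feedback (windows configurable; the underlying
response is biphasic with early dilation near 1 s and late constriction
near 2 s, and no exact scalar definition is canonical).

## Budgets and scaling

Tests and the acceptance suite scale simulation sizes to desk hardware
and say so where they do: synthetic raw traces at 100 Hz rather than the
generator's 1000 Hz default, reduced λ grids and CV splits, reduced
chain lengths, 12-subject end-to-end cohorts. Thresholds and tolerances
are asserted exactly as stated; only problem sizes shrink.
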