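---
title: "Context coding in primate calls: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context coding in primate calls: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callcontext)
```

`callcontext` packages two linked questions about a graded call type — here
modelled on the yawn vocalizations of adult male geladas — into one tested
pipeline:

1. **Expression**: does the acoustic structure of the call carry information
   about the social context in which it was emitted (high-social, low-social,
   non-social)?
2. **Perception**: do receivers respond differently to calls from different
   contexts, and does the receiver's own social engagement (grooming vs.
   solitary activity) modulate the response — in particular contagious
   yawning?

Because field recordings and coded videos are not redistributable, the
package ships a parametric simulator for both halves. This vignette explains
the statistical machinery, the simulator's assumptions, and every place
where the design was genuinely open.

## 1. The acoustic side

### Feature panel

`extract_features()` computes a ~32-feature panel covering the four families
that matter for a source–filter account of a mammalian call: temporal
(duration), intensity (per-frame RMS level in dB re full scale), source
(fundamental frequency: mean/median/SD/min/max/range, slope, voiced
fraction) and filter (median F1–F4 and formant dispersion), plus spectral
shape statistics (moments, quartiles, entropy, flatness, dominant
frequency). Field toolkits commonly extract an order of magnitude more
descriptors; the downstream statistics are panel-agnostic, so a compact
panel with one-to-one mappings onto the simulator's knobs is preferred here —
it makes feature-level *recovery* testable, which a grab-bag of redundant
descriptors would not be.

Numerical choices worth knowing:

* Spectral statistics are computed on the **Welch average periodogram**
  (Hann window, default 1024-sample frames, 50% hop), not averaged per-frame
  statistics, so results are bit-reproducible for fixed settings.
* The f0 tracker is a normalised-autocorrelation peak picker with parabolic
  lag refinement; a frame is voiced iff the peak is at least the
  `voicing_threshold` (default 0.45). Autocorrelation was chosen over
  cepstral tracking because it is transparent and directly testable on
  synthetic tones.
* Formants come from Yule–Walker linear prediction on pre-emphasised frames.
  Two details depart from the naive textbook recipe, both forced by testable
  failure modes: the signal is decimated to twice the 5 kHz formant ceiling
  before fitting (otherwise the pole budget is spent above the formant
  band), and near-coincident poles (< 200 Hz apart) are merged (a single
  strong harmonic otherwise masquerades as several narrow "formants"). The
  default order, `rate/1000 + 8`, is higher than the speech rule of thumb
  because a strongly harmonic source needs extra poles before root
  bandwidths tighten. Frames with fewer than four admissible poles
  (bandwidth < 400 Hz) are skipped, and the fraction of admissible frames is
  reported — an unfiltered tone yields 0 and flags itself.
* The dB reference is digital full scale. Absolute SPL calibration is out of
  scope.

### The Potential of Contextual Coding

For each feature, the within-context coefficient of variation uses the
small-sample correction

$$CV_w = 100\,\frac{s}{\bar X}\left(1 + \frac{1}{4n}\right),$$

the between-context CV is the uncorrected \(100\,s/\bar X\) over the pooled
sample, and

$$PCC = \frac{CV_b}{\operatorname{mean}(CV_w)},$$

with the **unweighted** arithmetic mean of the per-context CVs (this follows
the index's definition as "the mean CV across contexts"; an n-weighted mean
is a different statistic). A feature with PCC at or above 1 varies more
between contexts than within them and is a candidate carrier of context
information. The threshold is a parameter (`pcc_threshold`, default 1.0)
because the two natural conventions — strictly greater than 1 versus at
least 1 — differ in edge cases.

Under a pure-noise null the PCC distribution straddles 1 with its median
just below it (the correction factor inflates \(CV_w\)); about 30% of
independent noise features pass the PCC screen at the study's sample sizes.
The screen is a variance-ratio filter, not a significance test, and the
tests treat it as such.

### Three-step selection and its open questions

`select_features()` applies (i) the PCC screen, (ii) a Shapiro–Wilk
normality screen at `alpha_normality = 0.05`, and (iii) redundancy pruning:
surviving features are single-linkage clustered on \(1 - |r|\) and cut at
\(|r| \ge 0.9\); each cluster keeps one representative — the median-type
variant of a mean/median/SD family when present, otherwise the member with
the highest PCC. Every input feature appears exactly once in the audit
trail with the step and reason it was dropped or kept.

Open choices, resolved as follows and exposed as parameters:

* Normality is tested on **pooled** values by default (`normality =
  "per_context"` requires every context to pass instead). The pooled test is
  conservative in the interesting direction: a feature with a strong context
  effect can look non-normal pooled, which biases the pipeline *against*
  finding context coding rather than for it.
* The redundancy threshold (0.9) and linkage (single) are conventional and
  configurable; nothing downstream depends on ties within a cluster beyond
  the documented median-type preference.
* Features with missing values (e.g. formant medians of calls whose frames
  were all inadmissible) are dropped at step (i) with their own audit
  entry, since the discriminant model requires complete data.

### Discriminant classification against chance

`fit_dfa()` is the canonical linear discriminant: pooled within-class
covariance on the \(N - g\) denominator, axes from the eigenvectors of
\(W^{-1}B\) scaled to unit pooled within-class variance, classification by
smallest Mahalanobis distance adjusted by log prior. Priors are uniform by
default; chance assessment always uses class *proportions* regardless of
classifier priors, because that is what "assignment by chance" means for an
imbalanced pool. Ties break toward the lowest class index. A ridge of
\(10^{-8}\,\overline{\mathrm{diag}(W)}\) is added when the condition number
exceeds \(10^{10}\), with a warning.

`classify_loocv()` refits the model with each call held out; it is tested
against a literal refit-per-fold oracle and against an established LDA
implementation. Folds that would leave a class with fewer than two training
rows are flagged and excluded from denominators rather than silently
dropped.

`binomial_test()` evaluates exact tails by summation of binomial masses
(log-gamma arithmetic); the `greater` tail is the study's one-sided test of
above-chance assignment, and the two-sided variant (sum of outcomes no more
likely than observed) is available because, for published aggregate counts,
the two conventions can disagree about significance. `assess_classification()`
runs one test per class (successes = correct assignments, null = the class
proportion) plus a pooled test against \(1/g\).

One caveat the tests quantify rather than hide: held-out LOOCV predictions
share training sets, so the total-correct count is *overdispersed* relative
to a binomial — on chance-level data its variance is roughly 1.8× the
binomial value while its mean sits exactly at chance. An exact binomial
test on LOOCV counts (the field's standard assessment, and the one
implemented here) is therefore mildly anticonservative, with a type-I rate
near 10% at nominal 5% on a 90-call table. The full pipeline's type-I rate
stays below 8% only because the selection step usually retains little under
a true null; users wanting strict calibration should prefer a permutation
reference.

Variable contributions (`contribution_matrix()`) are Pearson correlations of
each feature with the discriminant scores, in long format for heatmap
plotting. Scores come from the full-data fit by default; held-out LOOCV
scores can be passed instead. The full-data default mirrors common practice
when per-fold scores are unavailable, while the argument exposes the cleaner
option.

## 2. The call simulator

`synth_call()` renders a harmonic source (linear f0 contour, cycle-wise
multiplicative jitter, spectral rolloff in dB/octave) through four cascaded
two-pole resonators, an attack/release envelope, and additive white noise at
a stated SNR. It is a *surrogate*, not a vocal-tract model: its purpose is
that every feature family the panel measures is independently manipulable,
so recovery and power tests have ground truth. Defaults (f0 150 Hz falling
30 Hz/s, formants at 700/1200/2400/3400 Hz, 3% jitter, 25 dB SNR, 1.2 s)
are in the range of a large-bodied monkey's tonal call.

`default_context_effects()` displaces the baseline per context: high-social
calls are longer (+6%), higher (+10 Hz) and slightly formant-shifted
(+1.5%); non-social calls are shorter (−5%), lower (−10 Hz) and fall faster
(−10 Hz/s); low-social is the baseline; a grunt control is much shorter
with a flatter, higher source. Variability has three nested levels, as in a
real pool: caller profiles add per-individual offsets (f0 ±8 Hz SD,
duration ±0.08 s SD, vocal-tract scale ±2% SD), drawn once per caller as a
deterministic function of caller id and seed; and every call adds its own
parameter-level variation (`call_sds`: f0 ±6 Hz, duration ±6%, slope ±4
Hz/s, formants ±1%) on top of the waveform-level jitter and noise. The
call-level layer matters statistically: without it, per-cell feature
distributions collapse onto caller point masses and a Shapiro–Wilk screen
at n ≈ 90 rejects every feature. Context-shift magnitudes are about one
within-cell SD, fixed once to put default classification clearly above
chance but far from ceiling at the study's pool sizes — the regime the
analysis is designed for. `scale = 0` removes all shifts and defines the
null pipeline used for type-I calibration.

What the simulator does **not** emulate: background noise structure of field
recordings, amplitude-dependent distortion, nonlinear phenomena
(subharmonics, deterministic chaos), and within-call arousal dynamics. A
pipeline that passes on synthetic calls is validated as *software* on a
signal whose generative structure matches the model's assumptions; it says
nothing about whether real calls satisfy those assumptions.

## 3. Stimuli, schedules, trials

`assemble_stimuli()` builds three-call sequences of one condition with two
pauses drawn uniformly from 5–10 s (a "randomized pause" with no stated
distribution; uniform is the maximum-entropy choice on the stated interval)
and equalises the three calls' peak amplitudes, reporting gain factors
rather than re-rendering audio. `schedule_playbacks()` assigns each of nine
subjects all four conditions in both receiver contexts under the field
constraints: at most three playbacks per day overall, at most one session
per subject per day (the 24-h spacing rule, modelled at day resolution
because spacing is only reported in day-scale bins), each stimulus
administered at most twice and never twice to the same subject, and no
subject ever hearing the same call in two stimuli. Re-use rules are split
between assembly (each call in at most two distinct stimuli, unique
combinations) and scheduling, which is the only reading of the combined
constraints that is feasible at the recorded pool sizes (the low-social pool
has 26 calls, but 18 sessions × 3 calls would need 54 call-administrations).
`validate_design()` re-checks every constraint independently of the
scheduler and returns the violated ones.

`generate_behavioral_dataset()` then draws, per session: baseline gaze and
self-directed-behaviour counts (Poisson, 2/min and 1/min), a zero-inflated
Poisson response increment on the log scale, and a Bernoulli yawn response
on the logit scale, with one shared N(0, σ²) subject intercept. Fixed-effect
defaults are the printed estimates of the study this package emulates (gaze:
intercept 1.192, sex 0.331, receiver −0.095, low-social 0.162, non-social
−0.938, trial order −0.184, σ_subject 0.1876; yawn: intercept −1.786, sex
−1.799, receiver 3.162, low-social −1.861, non-social −2.042, trial order
−0.184). Quantities never printed were fixed once: zero-inflation 0.2, the
grunt gaze offset −0.5, and the grunt yawn offset −1.479 (the logit gap
between the reported 55.6% and 22.2% descriptive response rates).

Two knowingly awkward points, kept rather than smoothed over:

* **Count differences.** The gaze response is a *difference* of counts yet
  is modelled as zero-inflated Poisson, which cannot represent negative
  values. The generator's default (`diff_mode = "floor0"`) makes the
  post-stimulus count equal baseline plus a nonnegative ZIP increment, so
  differences are ZIP-representable; `diff_mode = "raw"` draws the
  post-stimulus count directly and allows negative differences, which the
  fitting side then refuses with a pointer to
  `response_differences(floor_at_zero = TRUE)`. Which convention the
  original analysis used is not stated anywhere; both are provided and the
  choice is explicit in code.
* **The spontaneous floor.** Adult male geladas yawn spontaneously at up to
  0.25/min, which over a 3-min window implies a floor probability of
  \(1 - e^{-0.75} \approx 0.53\); the same literature also quotes a 3-min
  spontaneous probability of 20–25% (consistent with a ~0.1/min rate). The
  configuration default keeps the stated 0.25/min rate, and the evoked
  probability is mixed as \(p = p_{\mathrm{floor}} + (1 -
  p_{\mathrm{floor}})\,\mathrm{logit}^{-1}(\eta + b)\), so simulated yawn
  proportions sit above the published descriptive rates. This is a
  deliberate consequence of taking the stated rate at face value; users
  wanting the lower floor set `spontaneous_yawn_rate_per_min = 0.1`.

## 4. Mixed models

`fit_zip_mixed()` and `fit_logistic_mixed()` maximise the marginal
likelihood of a random-intercept GLMM by Gauss–Hermite quadrature (default
20 nodes; the log-likelihood changes by less than \(10^{-4}\) from 20 to 40
nodes on the test fixtures) with BFGS from GLM starting values plus jittered
restarts. Zero inflation is intercept-only on the logit scale — the
simplest structure consistent with "a Poisson model with zero inflation" —
and is exposed rather than hard-coded into interpretation. Variance
components are parameterised as \(\log\sigma\), so singular fits appear as
\(\sigma \to 0\) and are *reported* (`singular = TRUE`), not errors; in a
binomial fit, any fixed effect beyond ±15 on the logit scale sets the
`separation` flag, which is exactly how the pathological grooming-subset
model (18 observations, near-deterministic responses) manifests.

Two estimator facts the tests encode explicitly, because they are easy to
mistake for bugs:

* zi and σ are **boundary parameters**. On finite samples whose zero count
  or between-group spread happens to exceed expectation, their MLEs are
  legitimately positive even when the generating values are zero, and fixed
  effects shift accordingly. Reduction-to-GLM checks therefore condition on
  samples where the boundary collapses; the mixture likelihood itself is
  checked against an independent zero-inflated GLM implementation.
* The full-versus-control likelihood-ratio test at this design size (54
  observations, 9 subjects, 4 numerator df) is slightly anticonservative:
  its null rejection rate at α = 0.05 is near 7–9%, and an established
  Laplace-approximation fitter shows the same rate on identical data, so
  this is a property of chi-square asymptotics at n = 54, not of the
  quadrature implementation.

`likelihood_ratio_test()` compares nested fits (χ² floored at zero, df =
parameter-count difference). `pairwise_contrasts()` forms all level
differences with delta-method SEs from the Hessian-based covariance, and
adjusts either by Bonferroni (default) or the studentized-range (Tukey)
reference — the two adjustments the study text names together; the method is
recorded in the output. `vif_terms()` computes generalised VIFs
\(\det(R_t)\det(R_{-t})/\det(R)\) with the df-adjusted
\(\mathrm{GVIF}^{1/2\,df}\); on the balanced synthetic design all adjusted
values are below 2.5.

## 5. Problem sizes in the test and acceptance suites

Simulation sizes were fixed as the package's own trade-off between
Monte-Carlo error and runtime: type-I calibration of the acoustic pipeline
uses 200 replicate 30-call null pools; LRT null calibration uses 500
replicate behavioural datasets at the 9 × 6 design; fixed-effect recovery
uses 500 replicates at the 9 × 8 design; the power sweep uses four shift
scales × 6 replicate 90-call pools, classifying on the six features tied
directly to the manipulated knobs (a full 31-feature panel on a 30-row
table would make the within-class covariance singular — the sweep measures
power, not selection); and the behavioural emulation check uses 30
replicate campaigns with stimuli and schedules re-randomized per replicate,
because a single fixed schedule confounds trial order with the trigger
contrast in an 18-trial subset. Synthesis for tests runs at 8 kHz with
0.3–0.4 s calls — the panel's behaviour is rate-invariant apart from band
edges, and these sizes keep the whole suite inside a half hour.

## 6. Known limitations

* The acoustic simulator's context effects are additive/multiplicative
  displacements of independent knobs; real context effects are correlated
  through arousal and motor constraints.
* The zero-inflation structure is intercept-only; covariate-dependent
  inflation would need a second linear predictor.
* The scheduler is greedy with feasibility pre-checks; it reports
  infeasibility honestly but does not search exhaustively, so extremely
  tight stimulus pools can fail even when a satisfying assignment exists.
* Per-class accuracies from small per-class samples (n ≈ 20–40) carry wide
  binomial intervals; the pooled test is the primary inference, matching the
  study design this emulates.
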