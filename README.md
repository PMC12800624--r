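# callcontext

Does a graded animal call carry information about the social context in
which it was produced — and do listeners act on that information?
`callcontext` is an R package for bioacousticians and behavioural
ecologists that implements both halves of that question as one tested,
fully simulatable pipeline, modelled on playback studies of gelada yawn
vocalizations:

* **Expression side** — acoustic feature extraction from mono WAV calls
  (duration, intensity, spectral shape, fundamental frequency, formants);
  the *Potential of Contextual Coding*,
  `PCC = CVb / mean(CVw)` with the small-sample-corrected
  `CVw = 100 (s/x̄)(1 + 1/4n)`; a three-step feature selection
  (PCC ≥ 1 → Shapiro–Wilk normality → redundancy pruning at |r| ≥ 0.9);
  linear discriminant analysis with leave-one-out cross-validation; exact
  one-tailed binomial tests of each class's correct-assignment count
  against its class-proportion chance; and feature-by-axis contribution
  tables.
* **Perception side** — playback stimulus assembly and scheduling under
  field constraints (3-call stimuli, 5–10 s pauses, re-use limits, ≤3
  playbacks/day, 24-h per-subject spacing); simulated coded responses
  (gaze-count differences, self-directed behaviour, 3-min yawn responses);
  and zero-inflated Poisson / logistic mixed models with a subject random
  intercept fitted by Gauss–Hermite quadrature, with likelihood-ratio
  tests, generalised VIFs and Bonferroni/Tukey pairwise contrasts.
* **Simulator** — a parametric source–filter call generator (harmonic
  source with jitter, four formant resonators, envelope, noise) whose
  knobs map one-to-one onto the feature families, plus a behavioural trial
  generator whose default effect sizes are the published mixed-model
  estimates the package emulates. Everything downstream is testable with
  no field data.

## Worked example

Simulate a labelled call pool (5 callers × 6 calls × 3 contexts), extract
features, select context-informative ones, and classify with LOOCV:

```r
library(callcontext)

cfg <- synth_call_config(sample_rate_hz = 11025, duration_s = 0.8,
                         formant_centers_hz = c(700, 1400, 2600, 3500),
                         formant_bandwidths_hz = c(120, 150, 200, 250))
pool <- generate_call_dataset(n_callers = 5, calls_per_caller_per_context = 6,
                              context_effects = default_context_effects(),
                              seed = 42, base_config = cfg)
feats <- extract_table(pool$waveforms, frame_settings())
sel   <- select_features(feats)
lo    <- classify_loocv(feats, attr(sel, "retained"))
lo
assess_classification(lo)
```

```
<loocv_result: total correct 0.578 over 90 calls (0 flagged)>
             predicted
true          high_social low_social non_social
  high_social          18         10          2
  low_social            8         16          6
  non_social            3          9         18
         test  k  n    p0  p_value
1 high_social 18 30 0.333 2.46e-03
2  low_social 16 30 0.333 1.88e-02
3  non_social 18 30 0.333 2.46e-03
4       total 52 90 0.333 1.71e-06
```

The selection step kept 6 of 31 features (spectral centroid and quartiles,
median f0, median F1); 58% of held-out calls are then assigned to their
true context against a pooled chance of 1/3 (exact binomial p ≈ 2 × 10⁻⁶),
with most confusion between adjacent contexts — the moderate-separability
regime the default context effects are designed to produce. On a null pool
(`default_context_effects(scale = 0)`) the same pipeline retains little or
nothing and classifies at chance.

The perception side follows the same pattern: `assemble_stimuli()` →
`schedule_playbacks()` → `generate_behavioral_dataset()` →
`response_differences()` → `fit_zip_mixed()` / `fit_logistic_mixed()` →
`likelihood_ratio_test()` and `pairwise_contrasts()`. See the methods
vignette (`vignettes/context-coding-methods.Rmd`) for the models,
assumptions and every tunable default.

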