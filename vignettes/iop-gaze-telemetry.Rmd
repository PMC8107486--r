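---
title: "Analysing gaze- and eyelid-dependent IOP from continuous telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing gaze- and eyelid-dependent IOP from continuous telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iopgaze)
```

## The measurement problem

Implanted telemetric pressure sensors record intraocular pressure (IOP)
continuously at roughly 9 Hz, without touching the cornea. That makes it
possible to ask how IOP responds to ocular events that applanation tonometry
cannot follow: eccentric gaze held for a few seconds, the saccade that gets
the eye there, and eyelid closure. The experimental protocol this package
analyses is a fixation sequence on a tangent screen (a Harms wall): after a
baseline in the straight-ahead *primary* position, the subject fixates eight
targets — superior (S), superotemporal (ST), temporal (T), inferotemporal
(IT), inferior (I), inferonasal (IN), nasal (N), superonasal (SN) — at one
eccentricity (10°, 20° or 25°), 12 s per target, returning to the primary
position for 12 s between targets. Each eccentricity block starts with S,
proceeds clockwise, and closes with a repeat of S that serves as an internal
control for sequential effects; blocks are repeated three times. A subset of
subjects additionally closes their eyes for 10 s, four times, after a
baseline.

## The response measure

Raw telemetry mixes several components: the heart-beat-synchronous ocular
pulse (≈ 2 mm Hg peak-to-trough), a sharp transient at every saccade, slow
drifts of the measurement chain, and white noise. The analysis therefore
works on *baseline-referenced epoch means*:

* the first and last 2 s of every epoch are trimmed, leaving an 8-s analysis
  interval clear of the movement transients at the epoch borders;
* the response of a gaze epoch is
  $\Delta IOP = \overline{IOP}_{\text{gaze}} - \overline{IOP}_{\text{preceding primary}}$,
  so every epoch carries its own local reference and slow drifts largely
  cancel;
* for the within-epoch time course, the first and last 2 s *of the analysis
  interval* give $TW_{initial}$ and $TW_{final}$ (both referenced to the same
  baseline), and $d\Delta IOP = TW_{initial} - TW_{final}$ is positive when
  the response decays while the gaze is held;
* eyelid-closure epochs are summarised by the mean over the last 2 s of the
  10-s closure (after the initial closure spike has decayed) minus the
  preceding baseline mean.

Windows are half-open intervals $[start, end)$ in seconds from session
start. All internal arithmetic is full precision; rounding happens only in
the reporting layer.

Design choices worth making explicit:

* **Baselines are trimmed with the same 2-s rule as gaze epochs.** The
  return saccade contaminates the start of a baseline exactly as the outward
  saccade contaminates a gaze epoch, so the rule is applied symmetrically.
* **Dropped samples are never imputed.** Telemetry gaps (antenna
  misalignment) simply remove samples; a window failing quality control is
  excluded, not filled.
* **QC is a reproducible rule, not a judgment call**: a window fails when it
  retains fewer than half of its expected samples (`min_fraction = 0.5`,
  configurable) or overlaps a declared artifact span (e.g. a cough); a
  whole repetition can be dropped instead via `drop_repetition = TRUE`.
* **The closing control S epoch** is excluded from condition aggregation and
  used only by `internal_control_test()`.

## Inference

`analyze_cohort()` returns a classed fit carrying the full battery:

* **Group table** — repetitions are averaged within patient × condition
  first; group mean ± SEM (SD/√n over patients) per direction and
  eccentricity, plus an Overall row per eccentricity that averages the
  eight per-direction means.
* **Three-way within-subject RM-ANOVA** (`rm_anova_within()`) on the
  patient × direction × eccentricity × repetition table. All three factors
  are treated as within-subject, with subjects as the random blocking
  factor; each effect is tested against its own subject-interaction error
  term, $F = MS_E / MS_{E\times subj}$. Although one could call the factors
  "fixed", the design is fully repeated on every subject, and the
  effect-specific error strata are the standard reading. Missing cells are
  imputed by the subject's same-condition mean over the remaining
  repetitions (counted and flagged; degrees of freedom are not adjusted).
* **Greenhouse–Geisser correction.** For every effect with more than one
  degree of freedom, $\hat\varepsilon = (\mathrm{tr}\,C)^2 / (d\,
  \mathrm{tr}\,C^2)$ is estimated from the covariance $C$ of the effect's
  orthonormal within-subject contrasts (cells averaged over uninvolved
  factors), clipped to $[1/d, 1]$, and both the uncorrected p and the
  corrected `p_gg` (df scaled by $\hat\varepsilon$) are reported. We apply
  the correction to every such effect rather than gating it on Mauchly's
  test: reporting both p-values lets the reader apply either convention.
* **Post-hoc contrasts** — one-sample t-tests of the per-patient responses
  against zero, eight per eccentricity, Holm-corrected within the
  eccentricity family. `holm_adjust()` reports the step-down thresholds
  $\alpha/(m-k+1)$ (also rounded to three decimals, the convention for
  quoting an adjusted alpha next to a p-value), the step-down rejection
  flags, and Holm-adjusted p-values. Ties are broken by original index.
* **Vertical composites** — SNT = mean(SN, S, ST), INT = mean(IT, I, IN)
  per patient and eccentricity, computed from last-2-s responses when used
  in the eyelid comparison; tested against zero as one 7-test Holm family
  (six composites plus the eyelid response).
* **Eyelid vs downgaze** — patient-matched paired t of the eyelid response
  against the 25° INT composite. The single-direction variant (25° inferior)
  is available via `use = "inferior"`, since either comparison is
  defensible; the composite is the default because it is the more stable
  summary of "downgaze".
* **Individual-level contrast** — per patient, a paired t over
  repetition-matched responses of the two extreme directions (S vs IN at
  25°); with three repetitions this is deliberately coarse (df = 2) and is
  reported as an exploratory count of patients with p < 0.05.
* **Internal control** — paired t across patients of first-vs-closing S
  response per eccentricity. A purely additive session-long drift cancels
  in baseline-referenced responses by construction; this test is sensitive
  to changes in the *response* itself (e.g. a tonographic decline).
* **Normality** — a Shapiro–Wilk screen on the per-patient responses is
  recorded but never gates the pipeline.

Two-sided tests and $\alpha = 0.05$ throughout. A χ²-based comparison of
group means is deliberately out of scope: its contingency structure is not
well defined for this design.

## The synthetic telemetry generator

Because no raw patient telemetry is distributable, every stage is validated
against a generator with known ground truth
(`sim_params()` / `simulate_cohort()`):

$$IOP(t) = IOP_0 + \delta(\text{epoch}) + A\,e^{-(t-t_{on})/\tau}
  + \tfrac{OPA}{2}\sin(2\pi f_{HR} t) + \text{drift}(t) + \epsilon(t)$$

| parameter | default | meaning |
|---|---|---|
| `baseline_iop` | 16.5 mm Hg | primary-gaze IOP |
| `offset_table` | see `default_offset_table()` | plateau offset δ per direction × eccentricity |
| `pulse_amp` | 2.0 mm Hg | ocular pulse, peak-to-trough |
| `heart_rate` | 1.2 Hz | pulse frequency |
| `spike_amp`, `spike_tau` | 3 mm Hg, 2.5 s | saccadic transient (free parameters; 9 Hz sampling cannot pin the true spike height) |
| `eyelid_spike_amp`, `eyelid_tau` | 4 mm Hg, 2 s | closure transient, always positive |
| `eyelid_offset` | −2.1 mm Hg | steady-state closure response |
| `noise_sd` | 0.3 mm Hg | white measurement noise |
| `drift_sd` | 0.05 mm Hg/sample | random-walk drift |
| `rate_jitter` | 0.05 | fractional timestamp jitter around the 1/9-s grid |

Choices: the ocular pulse is a single sinusoid — only its amplitude and
heart-rate coupling are documented features, so richer waveforms would be
invented detail. The saccadic transient is signed toward the *new* plateau
(an overshoot-then-decay), while the closure transient is always positive.
Slow within-epoch decline is modelled generically by the random-walk drift
plus the decaying transient; no aqueous-dynamics model is attempted — the
biomechanics behind the decay is exactly what such data cannot yet decide.
Sampling times sit on a uniform 1/9-s grid with optional jitter, matching a
nominal "approximately 9 Hz" device.

Cohorts add between-patient structure: per-patient baseline, offset table
and eyelid offset are drawn as independent normal deviations around the
shared parameters. The default dispersions (`default_offset_dispersion()`)
are the between-patient SDs implied by cohort-level standard errors at
n = 11 (SD = SEM·√11), e.g. ≈ 4.9 mm Hg for the 25° superior response —
gaze responses genuinely differ a lot between people. Child seeds are
derived deterministically from the master seed (`derive_seed()`), so
cohorts are bit-reproducible and per-patient streams independent.

What the generator does *not* emulate: beat-to-beat heart-rate variability,
blink micro-events below the sampling resolution, correlated (gain-like)
patient response profiles, and any mechanistic coupling between the spike
and the plateau. Passing recovery tests therefore shows the *estimator* is
correct under the stated signal model, not that the model exhausts real
telemetry.

## Validation harness and problem sizes

`validate_recovery()` repeats simulate → segment → estimate:

* **Exactness**: with every stochastic and transient term off, the pipeline
  returns the configured offset table to machine precision — any
  discrepancy would be an indexing or pairing bug.
* **Recovery**: with default measurement noise (white noise + drift,
  spikes off so the plateau is the estimand, dispersion zero so the
  configured table is the truth), the worst per-condition RMSE over 20
  cohorts of 11 patients × 3 repetitions is ≈ 0.1 mm Hg, comfortably below
  the 0.3 mm Hg acceptance bound.
* **Calibration**: on 500 null cohorts (offset table all zero, every other
  parameter at its default, including the realistic between-patient
  dispersion), the GG-corrected direction effect rejects at ≈ 3–4% at
  nominal 5%. Two regimes are worth distinguishing: with the
  direction-heteroscedastic dispersion the within-subject covariance is
  genuinely non-spherical — the regime the correction is built for — and
  the test sits near (slightly under) nominal; under a fully iid null the
  GG test shows its textbook conservatism (≈ 2% at k = 8, n = 11) because
  $\hat\varepsilon$ is biased low when the contrast dimension approaches
  the subject count.

The test-suite problem sizes (e.g. 500 calibration replicates, 20 recovery
cohorts, 100 random tables for the F = t² identity) were chosen so each
property is measured with useful precision while the whole suite stays
quick to run.

## Worked example

```{r example, eval = FALSE}
library(iopgaze)

cfg <- run_config(seed = 42)          # 11 patients, 3 repetitions, 9 eyelid
fit <- run_full_analysis(cfg)
coef(fit)                              # direction x eccentricity response matrix
summary(fit)                           # group table, ANOVA, post-hocs, eyelid
plot(fit)

# recovery of the generator's truth
fit$recovery[order(-abs(fit$recovery$error)), ][1:5, ]
```

## Known limitations

* The individual-level contrast has df = 2 by design; its per-patient
  p-values are exploratory.
* Missing-cell imputation does not reduce the ANOVA degrees of freedom; with
  the small amounts of missingness the QC rules produce this is benign, but
  heavily incomplete tables deserve a mixed-model treatment that is out of
  scope here.
* The Holm thresholds rounded to three decimals are a reporting convention;
  the unrounded thresholds and adjusted p-values are what inference should
  use.
* `normality_screen()` is advisory; no non-parametric branch is provided.
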