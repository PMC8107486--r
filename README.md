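# iopgaze

Continuous intraocular-pressure (IOP) telemetry from implanted microsensors
makes it possible to measure how IOP responds to gaze direction and eyelid
closure — positional effects that applanation tonometry cannot follow.
`iopgaze` is an R package for analysing such recordings: it segments a
telemetry trace into protocol epochs, computes baseline-referenced IOP
responses, and runs the within-subject inferential battery appropriate for
a small repeated-measures cohort. A synthetic telemetry generator with
known ground truth makes every stage testable without patient data.

It is written for vision scientists and biostatisticians working with
event-locked physiological time series: the fitting function returns a
classed S3 object with `print`, `summary`, `coef`, `plot`, `residuals` and
`simulate` methods, in plain base R.

## The analysis in brief

A session alternates 12-s fixations at eight gaze directions
(S, ST, T, IT, I, IN, N, SN, clockwise from superior) with 12-s
primary-position baselines, at eccentricities of 10°, 20° and 25°, each
block repeated three times and closed by a control repeat of the superior
gaze; optionally four 10-s eyelid closures follow. For each epoch the first
and last 2 s are trimmed and the response is

```
ΔIOP = mean IOP(gaze epoch, 8-s interval) − mean IOP(preceding baseline)
```

Within-epoch dynamics are summarised by the first/last 2 s of the analysis
interval (TW_initial, TW_final) and their difference dΔIOP = TW_initial −
TW_final (> 0 when the response decays while gaze is held). Inference:
per-patient averaging over repetitions; group mean ± SEM per condition;
fully within-subject three-way repeated-measures ANOVA (direction ×
eccentricity × repetition) with effect-specific error terms and a
Greenhouse–Geisser sphericity correction, ε = (tr C)² / (d·tr C²) from the
covariance of orthonormal within-subject contrasts; Bonferroni–Holm
step-down post-hoc contrasts (threshold α/(m−k+1) at rank k); vertical
composites SNT = mean(SN, S, ST) and INT = mean(IT, I, IN); a
patient-matched eyelid-vs-downgaze paired t-test; a per-patient
extreme-direction contrast; and an internal-control test of first vs
closing superior gaze.

## Worked example

```r
library(iopgaze)

cfg <- run_config(seed = 42)   # simulate 11 patients x 3 repetitions, 9 with eyelid run
fit <- run_full_analysis(cfg)
fit
#> <iop_gaze_fit> 11 patient(s), 891 response records (0 QC-excluded)
#>   direction: F(7, 70) = 14.60, eps = 0.40, p_GG = 9.053e-06
#>   direction:eccentricity_deg: F(14, 140) = 1.88, eps = 0.29, p_GG = 0.1329
#>   eyelid vs downgaze: -1.93 +/- 0.58 mm Hg, p = 0.0108

round(coef(fit), 2)            # group-mean ΔIOP (mm Hg), direction x eccentricity
#>       10    20    25
#> S   2.01  5.13  4.53
#> ST  1.59  4.08  3.02
#> T   1.33  1.17  1.84
#> IT  0.60  0.85 -0.05
#> I  -0.51 -0.35 -1.28
#> IN -1.17 -1.59 -1.96
#> N  -1.04 -1.41  0.87
#> SN  1.19  1.24  3.42
```

The simulated cohort behaves like the real phenomenon: IOP rises in upgaze
(here +4.5 mm Hg at 25° superior), falls inferonasally (−1.96 mm Hg at
25°), the direction effect is strongly significant after sphericity
correction, and eyelid closure lowers IOP about 1.9 mm Hg below 25°
downgaze. `summary(fit)` prints the full group table, ANOVA, Holm-corrected
post-hocs, time-course correlation, internal control and eyelid tests;
`fit$recovery` compares every estimate against the generator's ground
truth.

Real recordings are analysed the same way from delimited text files
(`time_s,iop_mmhg` traces, `label,eccentricity_deg,start_s,end_s,repetition`
schedules) via `run_config("from-files", traces_dir = ..., schedules_dir =
...)`, or directly with `read_iop_trace()` / `read_schedule()` /
`analyze_cohort()`. A thin command-line wrapper with `simulate`, `analyze`
and `validate` subcommands is installed at `inst/cli/iopgaze`.

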