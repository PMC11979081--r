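---
title: "Methods: stump-pressure waveform analysis and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stump-pressure waveform analysis and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(stumpwave)
```

## Background and scope

During carotid endarterectomy (CEA) the internal carotid artery (ICA) is
clamped, and the pressure measured in the clamped stump reflects collateral
perfusion of the operated hemisphere — primarily through the circle of Willis
(CoW). `stumpwave` implements the full analysis chain for such recordings:

1. **Conditioning** of the 100 Hz pressure signal (10 Hz zero-phase low-pass,
   then second-order Savitzky-Golay smoothing over a 50 ms window).
2. **Cycle mapping and alignment** at an anacrotic fiducial (the maximum of
   the second derivative on the rising limb — the usual choice when no ECG
   channel is available).
3. **Two-step correlation-gated ensemble averaging**: a raw average of all
   aligned cycles, Pearson correlation of every cycle against it, retention of
   cycles with r > 0.95, and re-averaging into a representative beat.
4. **Morphometrics** of the representative beat: systolic/diastolic/pulse/mean
   pressure, the end-systolic (dicrotic notch) pressure, systolic and
   diastolic durations and areas, and the diastolic decay constant τ by the
   area method.
5. **Cohort statistics**: a rule-based CoW variant classifier, ICA/systemic
   pressure ratios, one-way ANOVA with Tukey HSD across variant groups,
   Pearson and Spearman correlations, and chi-square/Fisher tests.

Patient recordings are not distributed; a synthetic Windkessel pulse
generator with analytic ground truth drives all tests, so every stage is
verifiable end to end.

## The two-element Windkessel and the area method

In a two-element Windkessel, diastolic pressure decays exponentially toward
an asymptote $A$ with time constant $\tau = R\,C$ (peripheral resistance ×
total compliance):

$$P(t) = A + (P_0 - A)\,e^{-t/\tau}.$$

Integrating over any diastolic window $[t_1, t_2]$ gives the **area
identity**

$$\tau \;=\; \frac{\int_{t_1}^{t_2} \bigl(P(t) - A\bigr)\,dt}
                  {P(t_1) - P(t_2)},$$

which `tau_area()` evaluates with trapezoidal integration. The identity holds
exactly on *any* sub-window of a true exponential, a property we exploit for
guard intervals (below). The default asymptote is 0 mmHg (the plain
zero-asymptote reading of the area method); a fitted or physiological
asymptote can be supplied through the `asymptote` argument, since published
area-method variants differ on this point.

```{r tau-demo}
t <- seq(0, 3, by = 0.01)
tau_area(50 * exp(-t / 1.5), time_s = t)  # recovers 1.5 s
```

## The synthetic beat model

`beat_model_params()` defines a piecewise cycle chosen so that every
morphometric quantity has closed-form truth:

* a raised-cosine systolic upstroke from the beat foot to SBP over
  `upstroke_fraction` of the cycle;
* a raised-cosine descent from SBP to the notch pressure at
  `notch_fraction` of the cycle;
* a Windkessel diastole decaying from the notch pressure toward the
  asymptote with constant `tau` until cycle end.

Key defaults (all configurable): heart rate 60 /min, SBP 120 mmHg, DBP
80 mmHg, notch at 35% of the cycle at 95 mmHg, upstroke 15% of the cycle,
τ = 1.2 s, asymptote 0 mmHg. Recordings default to 60 s at 100 Hz, matching
the intraoperative acquisition setting the package targets.

**Continuity at the beat foot.** With a zero asymptote and physiological τ,
the truncated diastolic exponential ends well below the nominal DBP, so
resetting each cycle to DBP would put a large step discontinuity at every
foot; a 10 Hz zero-phase filter smears such a step over tens of milliseconds
and would corrupt foot timing and DBP readings by design rather than by
measurement. The generator therefore chains beats continuously — each
upstroke starts at the previous end-diastolic pressure — and, because the
end-diastolic value does not depend on the foot value, the whole recording is
generated in its periodic steady state. Ground truth (`TraceTruth`) reports
the *realized* foot pressure as `dbp_true`; the `dbp` parameter anchors the
first-beat shape and the parameter ordering constraints.

**Perturbations.** White measurement noise (`noise_sd`), a slow 0.05 Hz
sinusoidal baseline drift (`drift_amplitude`, below the beat frequency but
above DC, to stress foot detection realistically), and artifact beats: with
probability `artifact_rate` a cycle is replaced by its time-reversed form
rescaled by 0.6 toward the asymptote. A time-reversed cycle is provably
dissimilar to the template (the correlation gate is scale-invariant, so the
reversal — not the rescaling — carries the dissimilarity); the test suite
verifies r < 0.95 directly.

**What the generator does and does not emulate.** It reproduces beat-scale
morphology (upstroke, notch, exponential decay), stationary noise, slow
drift, and grossly aberrant beats. It does not emulate arrhythmia,
beat-to-beat variability of cycle length or amplitude, respiratory
modulation, wave reflections, a dicrotic *rebound* wave after the incisura,
or non-stationary artifacts. Passing tests therefore demonstrate correctness
of the algorithms under controlled morphology, not clinical robustness on
arbitrary recordings.

## Conditioning choices

* The 10 Hz low-pass is a 4th-order Butterworth applied forward-backward
  (`signal::filtfilt`), i.e. zero-phase, so fiducial timing is not shifted.
  The input is demeaned and mirror-padded (pad length 10·fs/cutoff samples)
  before filtering, which keeps the DC level exact and confines start-up
  transients to the discarded pad.
* The Savitzky-Golay window is converted to an odd sample count of at least
  5 (50 ms → 5 samples at 100 Hz). No padding is used here:
  `signal::sgolayfilt` falls back to one-sided polynomial fits at the trace
  ends, which preserves the polynomial-reproduction property everywhere
  (mirror padding would break it at the boundaries).
* Order is fixed: low-pass first, then Savitzky-Golay. Both stages are
  linear, so gains compose multiplicatively — asserted in the tests.

## Beat detection, alignment and averaging

Feet are detected as the pressure minimum immediately preceding each major
upstroke; upstrokes are local maxima of dP/dt with a 300 ms refractory period
and an adaptive threshold at 50% of the median upstroke peak slope. Cycles
outside a 0.3–2.0 s length gate are discarded, as are cycles without a valid
rising limb (< 1 mmHg rise). A non-pulsatile trace (< 5 mmHg excursion)
yields zero beats and a warning.

Cycles are aligned at the fiducial over a common support: a fixed 100 ms
pre-fiducial margin (which legitimately reaches into the preceding diastolic
tail — the foot sits a few samples before the fiducial) and the shortest
available post-fiducial span. Exactly two averaging passes are run: raw
average, gate at r > 0.95 (Pearson, full common support), re-average. At
least 5 retained beats are required (configurable); fewer raises an
"insufficient concordant beats" error carrying the per-beat correlations.
Heart rate is the median cycle length converted to beats/min.

## Notch detection and guard intervals

The dicrotic notch is searched between 50 ms after the systolic peak and 80%
of the cycle length. The primary rule takes the most prominent local
pressure minimum (the classical incisura). When no dip exists — the
generator's junction is a shoulder-type slope break — the fallback takes the
most prominent interior local minimum of the second derivative (the
concave-down curvature spike at the corner), refined by the centroid of the
curvature dip after removing a linear curvature background; a smoothly
decaying diastole has neither feature and is reported as "notch not found",
in which case durations, areas and τ are `NA` while amplitude features are
still returned.

The τ integration window starts 60 ms after the notch and stops 60 ms before
the cycle end. Both guards exist because the 10 Hz zero-phase filter smears
the notch corner and the next beat's upstroke over roughly ±50 ms; since the
area identity is window-invariant, the guards remove that contamination
without biasing the estimate. Both are configurable (`tau_guard_s`,
`tau_end_guard_s`).

With these choices the full pipeline — generation, filtering, detection,
averaging, notch, τ — recovers noise-free ground truth to within a fraction
of a mmHg for SBP/DBP and within 2% for τ across τ ∈ {0.5, 1, 2} s, and
stays within 2 mmHg and 5% under 2 mmHg measurement noise; these are exactly
the checks run by the test suite and `scripts/acceptance.R`.

```{r pipeline-demo}
sim <- generate_trace(beat_model_params(tau = 1.2, noise_sd = 1, seed = 1))
features <- analyze_trace(sim$trace)
dplyr::select(features, sbp, dbp, pp, inc_bp, tau, heart_rate, n_retained)
```

```{r pipeline-plot, eval = FALSE}
plot_waveform_panel(attr(features, "ensemble"))
```

## Circle-of-Willis classification

Segment states follow the 0.8 mm rule: `normal` at ≥ 0.8 mm, `hypoplastic`
below 0.8 mm, `absent` when not visualized. The anterior semicircle is
{contralateral A1, A-com, ipsilateral A1}; the posterior semicircle is
{P1, P-com} on both sides. Groups: 1 complete; 2 anterior compromised only;
3 posterior compromised only; 4 both semicircles compromised; 5 isolated
middle cerebral artery. Group 5 is an explicit path-interruption test: an
`absent` segment anywhere in the (serial) anterior route **and** an `absent`
ipsilateral posterior segment (P1 or P-com). Design choices where the
clinical definitions leave room:

* Group 5 takes precedence over group 4 (it is the extreme of "both
  compromised").
* "Both compromised" combinations that do not interrupt both collateral
  paths — including absent–absent ones — are group 4.
* Contralateral posterior segments count toward semicircle compromise but
  not toward the group-5 path test (the vertebrobasilar collateral reaches
  the operated side through the ipsilateral P1/P-com).
* Multiple non-normal segments confined to one semicircle stay in group 2/3,
  flagged via the `multi_segment` attribute.

The classifier is total and deterministic; the suite checks all 3^7 segment
combinations against an independently written rule-table oracle.

## The cohort simulator

`generate_cohort()` draws one record per subject across the five variant
groups. Defaults emulate a realistic CEA cohort of 78 subjects with group
sizes (12, 12, 31, 18, 5) and group-specific ICA stump pressure levels that
fall from the complete-CoW groups toward the isolated-MCA group (per-group
DBP means 51.5/50.7/40.7/38.9/35.0 mmHg, pulse-pressure means
23.4/27.7/18.9/12.2/11.7 mmHg, with matching between-subject SDs), a shared
radial (systemic) distribution, and a decay constant drawn identically in
every group (τ ~ 1.2 ± 0.35 s) — the simulator's null τ effect, mirroring
the empirical finding that collateral anatomy moves stump pressures but not
the diastolic decay rate.

Sampling details:

* DBP and PP are drawn from the group marginals and SBP = DBP + PP, so the
  realized SBP spread is the convolution of the two (the printed SBP column
  of a summary table is not jointly specified with DBP/PP).
* Positivity is enforced by *symmetric two-sided truncation* (reject outside
  (lo, 2·mean − lo)), which preserves the configured means exactly — a
  one-sided clip would bias the small-pulse-pressure groups upward by
  several mmHg.
* The incisura and mean pressures sit at calibrated fractions of the pulse
  pressure above DBP (0.46 ± 0.05 and 0.41 ± 0.05), which reproduces their
  observed group-level means from the DBP/PP draws.
* Backflow grade (1 weak/discontinuous, 2 continuous non-pulsatile,
  3 strong/pulsatile) follows a monotone group-conditional rule — more
  compromised circles draw weaker backflow — calibrated so the cohort-level
  Spearman correlation between backflow and CoW group is moderate and
  negative (around −0.35 under ordinal group coding 1–5).
* Contralateral stenosis is drawn independently of the waveform features
  (uniform 0–90%), matching the weak observed associations.

With `output = "traces"` each subject also carries simulated 60-s ICA and
radial recordings built from their drawn parameters, for exercising the full
signal pipeline rather than the feature shortcut.

## The statistical battery

`build_cohort_report()` runs, per feature: classical one-way fixed-effects
ANOVA (`stats::oneway.test`, equal variances) across CoW groups and Tukey HSD
pairwise comparisons (`stats::TukeyHSD`); Pearson correlation of
contralateral stenosis against each feature; Spearman rank correlation
(mid-ranks for ties) of backflow grade against CoW group; and a
chi-square/Fisher test of the backflow-by-group table. Conventions:

* Chi-square (no continuity correction) requires every expected cell count
  to exceed 5; otherwise Fisher's exact test for 2×2 tables, chi-square with
  a warning for larger sparse tables.
* Groups with fewer than 2 observations are excluded with a warning; fewer
  than 2 usable groups is an error.
* No multiple-testing correction is applied across features; Tukey adjusts
  within each feature's family of pairwise contrasts only.
* α defaults to 0.05 and is recorded on the report.

```{r cohort-demo}
cohort <- generate_cohort(cohort_sim_params(seed = 7))
report <- build_cohort_report(cohort)
report
glance(report)
```

## Problem sizes and numerical tolerances

The test suite and acceptance script use 60-s, 100 Hz recordings (6000
samples, ~60 beats) for signal-level checks; 1000 replicates for the ANOVA
type-I-error check; 200 replicate cohorts of 78 subjects for the group-effect
pattern; and the full 3^7 = 2187 enumeration for the classifier. These sizes
keep each check comfortably converged (binomial standard errors of 0.7–1.5
percentage points on the rate checks) while the whole suite runs in well
under a minute. Floating-point assertions use tolerances tied to the
dominant numerical error: trapezoidal integration error at 100 Hz (< 0.1%
for τ), filter-induced distortion at slope-break corners (≤ 1 mmHg on
amplitudes), and 1e-6 or tighter where quantities are exact by construction.

## Known limitations

* The notch detector assumes a single systole-diastole transition; bisferiens
  or heavily reflected waveforms are out of scope.
* The area-method τ is only as good as the asymptote assumption; with the
  default asymptote 0 it is exact for the generator but will be biased on
  decays toward a nonzero floor unless `asymptote` is set accordingly.
* The classifier encodes one defensible reading of the variant definitions
  where they are ambiguous (documented above); alternative readings change
  only the group-4/5 boundary.
* Cohort records draw features directly by default; trace-backed cohorts are
  supported but slower, and the feature shortcut bypasses pipeline noise.
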