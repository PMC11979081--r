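# stumpwave

Analysis of intraoperative **internal carotid artery (ICA) stump pressure
waveforms** recorded during carotid endarterectomy, and of the cohort-level
statistics that relate those waveforms to **circle of Willis (CoW)
morphology**.

When the carotid artery is clamped during endarterectomy, the pressure in the
clamped ICA stump is sustained only by collateral flow — chiefly through the
circle of Willis. Its pulse waveform therefore carries information about how
well the operated hemisphere is perfused: stump systolic/diastolic/pulse
pressures (absolute and as ICA/systemic ratios), waveform areas, and the
diastolic decay constant of a two-element Windkessel,

$$P(t) = A + (P_0 - A)\,e^{-t/\tau}, \qquad \tau = R\,C,$$

estimated by the **area method**
τ = ∫(P − A) dt / (P_start − P_end), which is exact for an exponential
decay and markedly noise-tolerant. The package is aimed at researchers in
cerebrovascular hemodynamics and perioperative monitoring who need a tested,
reproducible implementation of this processing chain — and at anyone who
wants to study its statistical behaviour on simulated cohorts, since no
patient data ship with the package.

## What it does

* **Synthetic ground truth** — `generate_beat()`, `generate_trace()`,
  `generate_cohort()`: a piecewise raised-cosine/Windkessel beat model with
  closed-form truth for every derived quantity; 60-s, 100 Hz recordings with
  noise, baseline drift and injected artifact beats; cohorts with five CoW
  variant groups, group-conditional backflow grades and stenosis.
* **Signal conditioning** — `preprocess_trace()`: 10 Hz zero-phase
  Butterworth low-pass, then second-order Savitzky-Golay smoothing (50 ms
  window).
* **Beat analysis** — `segment_beats()`, `locate_fiducial()`,
  `ensemble_average()`: cycle mapping, second-derivative anacrotic fiducials,
  and two-step ensemble averaging with a Pearson r > 0.95 retention gate.
* **Morphometrics** — `detect_dicrotic_notch()`, `extract_features()`,
  `tau_area()` / `estimate_tau_area()`, `compute_pressure_ratios()`:
  the full waveform panel (SBP, DBP, PP, MBP, incisura pressure, systolic and
  diastolic durations and areas, τ, heart rate) and ICA/radial ratios;
  `analyze_trace()` runs the whole chain.
* **Cohort statistics** — `classify_cow()`, `build_cohort_report()` with
  `anova_oneway()`, `tukey_hsd()`, `correlate()`, `categorical_test()`:
  the rule-based five-group CoW classifier (0.8 mm segment rule) and the
  ANOVA/Tukey/Pearson/Spearman/chi-square-Fisher battery, with broom-style
  `tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

Simulate a noisy 60-s stump recording with known τ = 1.2 s, run the full
pipeline, and read off the morphometric panel:

```r
library(stumpwave)

sim <- generate_trace(beat_model_params(sbp = 120, dbp = 80, tau = 1.2,
                                        noise_sd = 1, seed = 1))
features <- analyze_trace(sim$trace)
dplyr::select(features, sbp, dbp, pp, mbp, inc_bp, tau, heart_rate, n_retained)
#> # A tibble: 1 × 8
#>     sbp   dbp    pp   mbp inc_bp   tau heart_rate n_retained
#>   <dbl> <dbl> <dbl> <dbl>  <dbl> <dbl>      <dbl>      <int>
#> 1  120.  55.3  64.8  82.9   94.8  1.21         60         58
```

The estimate τ̂ = 1.21 s recovers the configured 1.2 s; SBP and the notch
pressure (95 mmHg configured) are recovered to well under 1 mmHg; the DBP of
55.3 mmHg equals the generator's realized end-diastolic foot pressure
(`sim$truth$dbp_true`), and 58 of the ~60 cycles pass the r > 0.95 gate.

Simulate a cohort with the default five-group structure and run the
statistical battery:

```r
cohort <- generate_cohort(cohort_sim_params(seed = 7))
report <- build_cohort_report(cohort)
report
#> <cohort_report> 78 subjects, alpha = 0.05
#>   ANOVA across CoW groups: 17 features, 10 significant (ica_sbp, ica_dbp,
#>   ica_pp, ica_mbp, ica_inc_bp, ratio_sbp, ratio_dbp, ratio_pp, ratio_mbp,
#>   ratio_inc)
#>   Spearman backflow ~ CoW group: rho = -0.436 (p = 6.49e-05)

dplyr::filter(tidy(report), feature %in% c("ica_pp", "ica_tau", "ratio_sbp"))
#> # A tibble: 3 × 7
#>   feature   statistic   df1   df2      p_value n_obs n_groups
#>   <chr>         <dbl> <dbl> <dbl>        <dbl> <int>    <int>
#> 1 ica_pp       13.8       4    73 0.0000000192    78        5
#> 2 ica_tau       0.353     4    73 0.841           78        5
#> 3 ratio_sbp     9.36      4    73 0.00000364      78        5
```

This shows the qualitative pattern the simulator is built around: stump
pulse pressure and the ICA/systemic ratios differ strongly across CoW
variant groups, backflow weakens as the circle degrades (negative Spearman
rho), while the diastolic decay constant — drawn identically in every group
— shows no group effect.

The methods vignette (`vignettes/stump-waveform-methods.Rmd`) documents the
beat model, the filter and guard-interval choices, the classifier rules and
the simulator's sampling scheme in detail.

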