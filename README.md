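# fnirsupb

Detecting unplanned purchase behavior from prefrontal fNIRS signals.

## What this is

Unplanned purchase behavior (UPB) — buying on impulse under promotions such
as Buy-One-Get-One-Free (BOGOF) — is traditionally measured by interviews
and questionnaires, which depend on what people notice and remember.
`fnirsupb` implements, as a tested and fully seeded R pipeline, a
neuroimaging alternative: classify from prefrontal functional near-infrared
spectroscopy (fNIRS) whether a shopping trial was performed under the
promotion (Task 1, eliciting UPB) or without it (Task 2, control), subject
by subject, and report how reliable that classification is. It is aimed at
researchers in neuroergonomics / consumer neuroscience who want a
reproducible reference implementation of this analysis, complete with a
synthetic-data generator so every stage can be exercised and tested without
access to any recordings.

The chain, per subject:

1. dual-wavelength (780/850 nm) optical density at 8.138 Hz, 15 prefrontal
   channels (5 sources, 7 detectors, 3 cm separation; DLPFC, VLPFC left and
   right, mPFC, OFC);
2. zero-phase band-pass 0.01–0.1 Hz;
3. modified Beer–Lambert conversion,
   ΔOD(λ) = [ε_HbO(λ)·ΔHbO + ε_HbR(λ)·ΔHbR]·d·DPF(λ), solved per sample
   for (ΔHbO, ΔHbR); ΔHbO only is analyzed further;
4. epochs −1…60 s around task onsets, baseline-corrected on [−1, 0) s;
5. six time-domain features per (channel, trial) epoch —
   SM = (1/N)Σxₙ, SV = Σ(xₙ−μ)²/(N−1), KR = E[((x−μ)/σ)⁴],
   SK = E[((x−μ)/σ)³], SS (mean per-sample slope), SA = Σxₙ·Δn —
   min-max rescaled to [0, 1] with the scaler fitted on training folds only;
6. linear SVM (maximum margin 2/‖w‖, C = 1) under 30 stratified 80/20
   train/test splits: accuracy mean ± SEM;
7. ROC/AUC from pooled held-out decision values (TPR = TP/(TP+FN),
   FPR = FP/(FP+TN), trapezoidal area = Mann–Whitney ranking probability);
8. verdict: READY to detect UPB patterns only if accuracy strictly
   exceeds 80%.

A behavioral arm summarizes purchase counts (5 clothing categories × up to
4 items, totals 0–20 per task) and 3-item 5-point Likert self-reports, and
compares conditions with pooled-variance independent-samples t-tests.

The synthetic generator builds block-design recordings (1 s cue, 25 s task,
rest; 5 trials per task) from a double-gamma hemodynamic response scaled by
per-ROI amplitudes, pushes them through the forward Beer–Lambert model, and
adds cardiac/respiratory/Mayer oscillations, drift and white noise in the
optical-density domain. See the methods vignette
(`vignettes/upb-detection-methods.Rmd`) for every parameter, default and
design choice.

## Worked example

```r
library(fnirsupb)

res <- run_pipeline(sim_config(n_subjects = 10, seed = 1), cv_repeats = 30)
res
#> <upb_results> 10 subject(s)
#>   grand accuracy: 91.76% +/- 0.62% (SEM)
#>   mean AUC: 0.99  READY: 10/10

glance(res$auc)
#> # A tibble: 1 x 5
#>    mean      sd     sem   min   max
#>   <dbl>   <dbl>   <dbl> <dbl> <dbl>
#> 1 0.985 0.00737 0.00233 0.970 0.990

res$behavior$t_total
#> # A tibble: 1 x 4
#>       t    df        p degenerate
#>   <dbl> <dbl>    <dbl> <lgl>
#> 1  4.89    18 0.000119 FALSE

res$likert$t_test
#> # A tibble: 1 x 3
#>       t    df       p
#>   <dbl> <dbl>   <dbl>
#> 1  3.85    18 0.00119
```

Reading this: across 10 simulated subjects the per-subject SVMs average
91.76% held-out accuracy (SEM over subjects 0.62%), the per-subject AUCs
average 0.985 (range 0.97–0.99), and every subject clears the 80% readiness
threshold, so each would receive the "ready to detect unplanned purchase
patterns" message. The behavioral tables show the programmed contrast:
subjects "buy" more under the promotion (t(18) = 4.89) and report a stronger
compulsive desire to buy (t(18) = 3.85).

Useful building blocks: `simulate_recording()`, `bandpass()`,
`od_to_hemoglobin()`, `epoch_hemo()`, `baseline_correct()`,
`build_feature_matrix()`, `cross_validate()`, `roc_auc()`,
`detection_verdict()`, `t_from_summary()`; `tidy()`/`glance()` methods and
`autoplot()`/`plot_accuracy()`/`plot_epoch_means()` for results.

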