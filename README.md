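# copingtrace

Analysis of active/passive coping behavior and habenular astrocyte calcium
signals, for labs quantifying behavioral-state transitions in head-fixed
mice and head-restrained zebrafish.

Under an inescapable challenge, animals alternate bouts of vigorous
struggling — **active coping (AC)** — with quiescent **passive coping
(PC)** periods, and habenular astrocytes show calcium elevations locked to
the AC bouts. `copingtrace` implements the full analysis chain around that
phenomenon:

* **Bout segmentation** — amplitude- and duration-thresholding of low-pass
  filtered motion-index or velocity traces into an alternating AC/PC
  partition: binarize at threshold *a* (0.5 a.u. default), merge
  sub-threshold gaps shorter than the minimum PC duration (0.5 s), prune
  active runs shorter than the minimum AC duration (2 s spontaneous, 2.7 s
  evoked), emit the partition. Open-field velocity events (6 cm/s, ≥ 1 s,
  ≥ 2 s preceding quiet) and evoked-response probabilities included.
* **Fiber photometry** — exponential smoothing (τ = 0.1 s), isosbestic
  motion-artifact correction `(F − iso_fit)/iso_fit` with the 405 nm
  channel affine-fitted onto the signal channel, per-trial z-scoring
  against pre-event baselines `z(t) = (x(t) − μ_base)/σ_base` (3 s stimulus
  / 5 s spontaneous), duration-sorted event-aligned matrices, per-animal
  normalization, last-second AC-vs-PC amplitude comparison (Wilcoxon
  signed-rank), onset-to-peak rise times regressed on bout duration,
  dual-signal onset latencies, and 1 Hz calcium–velocity correlograms.
* **Zebrafish two-photon** — tail-angle swim-bout detection (> 0.65 rad,
  > 1 s), Otsu pixel masking, 10×10 binning with ΔF/F = (F − F₀)/F₀,
  responsive-bin selection by one-tailed signed-rank on paired
  baseline/response window means, and bout- and stimulus-locked
  quantification of the mean responsive-bin signal.
* **Decision-rule statistics** — Shapiro–Wilk-gated test routing
  (t/ANOVA vs signed-rank/Mann–Whitney/Kruskal–Wallis), the saline→CNO
  sign-inversion repeated-measures ANOVA for chemogenetic experiments, and
  rabies-tracing inclusion filters (> 5 cells on 2 adjacent sections in
  more than 3 animals; > 30% spread / > 0.5% neuronal starter exclusion).
* **Synthetic generators** — seeded, ground-truthed motion sessions,
  two-channel photometry, two-photon movies with a programmed responsive
  region, and alternating-injection session tables, emulating the signal
  structure every stage assumes so the whole pipeline is testable offline.

The signed-rank test used throughout fixes Pratt zero handling and the
exact null distribution for n ≤ 25, so p-values are reproducible on tied
data.

## Worked example

Simulate a six-minute head-fixed session, segment it, and quantify the
bout-locked calcium transients:

```r
library(copingtrace)

cfg <- generator_config(seed = 42)
sim <- gen_motion_session(cfg)              # trace + ground truth
seg <- detect_bouts_filtered(sim$trace)     # 0.5 Hz low-pass, then segment
head(seg, 5)
#>   state start  end duration
#> 1    PC   0.0 13.2     13.2
#> 2    AC  13.2 17.0      3.8
#> 3    PC  17.0 23.7      6.7
#> 4    AC  23.7 29.5      5.8
#> 5    PC  29.5 66.7     37.2

s <- summarize_bouts(seg, bin_s = 60)
sprintf("total AC: %.1f s in %d bouts", s$total_active_s, s$n_active_bouts)
#> "total AC: 51.4 s in 12 bouts"

ph  <- gen_photometry_session(cfg, sim$truth)
dff <- photometry_preprocess(ph$session)    # smooth + isosbestic-correct
mat <- build_aligned_matrix(dff, ac_events(seg), baseline_s = 5)
fit <- rise_duration_regression(rise_points(mat, post_margin_s = 1))
sprintf("rise ~ duration: slope %.2f (95%% CI %.2f-%.2f), R2 = %.2f",
        fit$slope, fit$slope_ci[1], fit$slope_ci[2], fit$r_squared)
#> "rise ~ duration: slope 0.79 (95% CI 0.70-0.87), R2 = 0.98"

cmp <- state_amplitude_comparison(dff, seg)
sprintf("last-second z: AC %.1f vs PC %.1f, signed-rank p = %.3g",
        mean(cmp$pairs$ac_last), mean(cmp$pairs$pc_last), cmp$test$p.value)
#> "last-second z: AC 18.5 vs PC -0.2, signed-rank p = 0.000488"
```

The session was generated with a programmed rise-time slope of 0.8 and
AC-locked transients, and the recovered regression (slope 0.79, CI covering
0.8) and strongly positive AC-vs-PC contrast show the chain recovering
those ground truths. Real recordings enter the same functions through
`read_trace_csv()`, `read_photometry_csv()`, and `read_movie_tiff()`.

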