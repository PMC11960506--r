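# dosegrammar

Tools for measuring and explaining how regulatory elements (REs) respond to
transcription factor (TF) dosage.

When a TF is titrated from 100% down to 0% of its normal level (for example
with a degron system) and chromatin accessibility is read out by ATAC-seq,
individual REs respond very differently: *buffered* elements hold their
accessibility until the TF is nearly gone, while *sensitive* elements lose
accessibility as soon as dosage drops. `dosegrammar` implements the
quantitative machinery for this kind of experiment:

- **Dose-response fitting.** Per-RE curves are fitted with the Hill
  equation, `y(d) = y_min + (y_max − y_min)·d^h / (K^h + d^h)`, with the
  endpoint values fixed to the mean response at 0% and 100% dosage (a
  three-parameter variant with a free maximum is adopted when its AIC
  improves by more than 2). The headline statistic is a *modified ED50*:
  the dosage (in percent) at which the fitted curve reaches 50% of its
  value at 100% dosage — capped at 100 by construction, avoiding the
  instability of plateau-based ED50s for very sensitive elements. REs are
  classified buffered (ED50 < 30) or sensitive (ED50 ≥ 30). Preprocessing
  follows standard ATAC practice: CPM normalization (optionally TMM),
  per-RE batch regression, max-absolute scaling, and |Z| > 3 outlier
  removal.
- **TF–nucleosome competition (NMC) model.** An equilibrium
  statistical-mechanics model in which TFs and a nucleosome compete for
  the same DNA. With per-site effective concentrations `α_s = [TF]/K_D,s`,
  nucleosome/open equilibrium constant `L`, and competition parameter `c`
  (fold suppression of TF binding on nucleosomal DNA),

      Acc = Π_s (1 + α_s)^{n_s} / [ Π_s (1 + α_s)^{n_s} + L·Π_s (1 + c·α_s)^{n_s} ]

  The package computes forward accessibility curves (homotypic, mixed
  high/low-affinity, and two-TF configurations), theoretical ED50s, the
  minimal K_D ratio at which adding a weaker second site *sensitizes* the
  response, a closed-form two-TF ED50, and bounded least-squares fitting
  of (c, α_max, K_D ratio) to observed dose-response curves with the
  quality filter MSE ≤ 0.001 (0.01 for two-TF fits) and c ≥ 0.
- **Motif-instance mapping.** Contribution weight matrices (CWMs, signed
  per-base attribution motifs) are scanned across contribution-score
  tracks using a sign-aware continuous Jaccard similarity, with permissive
  percentile thresholds (Jaccard ≥ 10th percentile, total absolute
  contribution ≥ 0.5th percentile), length-weighted overlap resolution,
  summit-distance statistics, and location-shuffled controls. PWM scanning
  uses log-odds scores with *exact* p-values from a dynamic-programming
  enumeration of the background score distribution.
- **Synthetic data with ground truth.** Every input the pipeline consumes —
  titration count matrices, contribution tracks with planted CWM
  instances, sequences with planted PWM sites, and forward-model response
  curves — can be generated with recorded ground truth, so all estimators
  are benchmarked end to end without external data.

## Worked example

A noiseless titration with true parameters `K = 0.5`, `h = 1`, `y_min = 0`
has `y(1) = 1/1.5 = 2/3`; half of that is reached at dosage 0.25, so the
modified ED50 is 25%:

```r
library(dosegrammar)
d <- rep(c(0, 0.22, 0.45, 0.75, 1), each = 4)   # five dosages, four replicates
fit <- fit_hill(d / (0.5 + d), d)
fit
#> <hill_fit> three_param: K = 0.5, h = 1, y_min = 0, y_max = 1
modified_ed50(fit)
#> [1] 25
classify_response(modified_ed50(fit))
#> [1] "buffered"
```

On the theory side, scanning the K_D ratio of a second binding site under
strong TF–nucleosome competition shows that a ~10-fold weaker site already
makes the response *more* sensitive (raises the ED50), while without
competition every second site buffers:

```r
sensitizing_threshold(L = 1000, c = 0.01)
#> <sensitizing_scan> L = 1000, c = 0.01; single-site ED50 = 90.83
#>   minimal sensitizing K_D ratio: 10
sensitizing_threshold(L = 1000, c = 0)
#> <sensitizing_scan> L = 1000, c = 0; single-site ED50 = 981.4
#>   no K_D ratio on the grid sensitizes (every second site buffers)
```

An end-to-end synthetic run (simulate → fit → classify → competition-model
fit → motif mapping) is one call:

```r
res <- run_pipeline(run_config(seed = 1), out_dir = "run1")
make_report("run1")
```

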