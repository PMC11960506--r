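---
title: "Models and methods behind dosegrammar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dosegrammar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosegrammar)
```

`dosegrammar` quantifies how chromatin accessibility at regulatory elements
(REs) responds to titration of a transcription factor (TF), and interprets
those responses with an equilibrium model of TF–nucleosome competition and
with motif-instance mapping on attribution tracks. This vignette documents
the models, their assumptions, the tunable parameters, and the numerical
choices, so a user can judge what the package's results do and do not mean.

## Dose-response curves and the modified ED50

Each RE's accessibility across a TF titration (dosage `d` as a fraction of
the unperturbed level, 0–1) is summarized by the increasing Hill form

$$y(d) = y_{\min} + (y_{\max} - y_{\min})\,\frac{d^h}{K^h + d^h}.$$

**Preprocessing.** Counts are normalized to CPM (optionally with TMM
effective library sizes via edgeR), batch effects are removed per RE by
least-squares regression on batch indicators (the grand mean is added back
so levels are preserved), values are scaled by the maximum absolute value
across samples, and samples with |Z| > 3 (sample SD of the scaled vector;
the population/sample distinction is immaterial at 20 samples and we fix
the sample convention) are masked. An all-zero RE is skipped with a logged
reason rather than fitted.

**Model selection.** A two-parameter fit (free `K`, `h`; endpoints fixed to
the mean scaled response at dosage 0 and 1) is always computed, along with
a three-parameter fit with a free maximum. The three-parameter model is
adopted only when its AIC improves by more than 2. AIC is computed under a
Gaussian likelihood with the variance profiled out,
`AIC = n·log(RSS/n) + 2k`; because this expression degenerates as RSS → 0,
RSS is floored at 1e-12 (scaled-response units) so that numerically perfect
fits resolve toward the more parsimonious model rather than amplifying
meaningless RSS ratios. Fitting uses bounded Levenberg–Marquardt least
squares (`minpack.lm::nlsLM`) with multi-start initialization over
`K ∈ {0.1, 0.3, 0.5, 0.7}` and `h ∈ {1, 3}`; bounds are
`K ∈ [1e-4, 100]`, `h ∈ [0.05, 50]`. If no start converges the RE is
reported `converged = FALSE`, never with a silent estimate. A flat response
(endpoint means indistinguishable at 1e-8 relative) is likewise refused,
since `h` is unidentifiable there.

**Modified ED50.** The reported ED50 is the dosage (as a percent) at which
the *fitted* curve reaches 50% of its fitted value at 100% dosage — not
50% of the theoretical plateau. Because the root is sought on `(0, 1]` by
bisection (tolerance 1e-9 in dosage units), the value is capped at 100 by
construction; this avoids the unstable, unbounded ED50s that plateau-based
definitions produce for very sensitive REs, exactly the regime of interest.
When the fitted baseline already exceeds the half-level the ED50 is
undefined and returned as `NA` with a reason. Curves whose fitted maximum
falls below the baseline are rejected as non-monotone. REs are classified
*buffered* when ED50 < 30 and *sensitive* otherwise; exact ties at the
threshold go to *sensitive* and are reported.

## The TF–nucleosome competition model

A stretch of regulatory DNA is either nucleosome-bound or open, with
equilibrium constant `L` (dimensionless; fixed at 10^3 in all fits,
exposed as a parameter for sensitivity analysis) favouring the bound state
in the absence of TFs. TFs bind `n_s` sites of class `s` with effective
concentration `α_s = [TF]/K_{D,s}`; binding on nucleosomal DNA is
suppressed by the competition parameter `c ∈ [0, 1]` (the ratio of motif
affinities between nucleosome-bound and free DNA). Steady-state
accessibility is

$$\mathrm{Acc} = \frac{\prod_s (1+\alpha_s)^{n_s}}
{\prod_s (1+\alpha_s)^{n_s} + L\,\prod_s (1+c\,\alpha_s)^{n_s}},$$

which satisfies the structural identities the implementation is tested
against: `Acc(0) = 1/(1+L)` for every site configuration, a flat curve at
`c = 1`, monotone nondecreasing in α for `c < 1`, and reduction of the
mixed and two-TF forms to the homotypic form in the appropriate limits.
Evaluation is in log space so large `α·n` cannot overflow.

**Theoretical ED50.** α is titrated over `[1e-5, 1e5]` (20 log-spaced
points per decade), and the ED50 is the α at which accessibility reaches
halfway between its values at the bottom and top of the window, refined by
bisection between the bracketing grid points. This mirrors the data-side
modified-ED50 convention (half of the response at the top of the
titration), which matters because observed Hill curves — parametrized by
that same convention — are the fitting targets.

**Sensitizing threshold.** Starting from a single high-affinity site
(`K_D = 1`), the K_D ratio of an added second site is scanned and the
smallest ratio at which the two-site ED50 *exceeds* the single-site ED50
is reported. Two deliberate choices:

- The default ratio grid is decade-spaced (1, 10, …, 10^5). The question
  this scan answers — how many *orders of magnitude* weaker can a site be
  and still sensitize — is an order-of-magnitude question, and the model's
  inputs (relative affinities of degenerate motif variants) are not known
  to better precision. The continuous crossover is available via
  `refine = TRUE`.
- A sensitization call requires the two-site ED50 to exceed the
  single-site value by a 1% relative margin. When the second site's K_D
  approaches the top of the α window, the site's only effect is to perturb
  the reference level at the window edge, producing spurious sub-0.01%
  ED50 "increases"; genuine sensitizing shifts in this model are tens of
  percent and larger. The margin suppresses the boundary artifact without
  touching real signals.

At `c = 0` no ratio sensitizes (a second site always buffers); the scan
returns `NA` rather than a number.

**Two-TF ED50, closed form.** For one site per TF with the second TF held
at `α₂`, write `A = 1 + α₂`, `B = L(1 + cα₂)` and let `m` be the
half-level `(Acc(α_min) + Acc(α_top))/2`. Solving `Acc(α) = m` exactly
gives `α* = (R − 1)/(1 − Rc)` with `R = mB/(A(1−m))`. The numeric root is
treated as normative; the closed form is verified against it to 1e-8
relative in the test suite, and is strictly decreasing in `α₂` for
`c < 1` — a second TF always buffers, with or without nucleosome
competition.

**Fitting recipes.** Observed curves enter the fits as normalized targets:
a Hill curve built from a fitted (ED50, h) pair, scaled so the response at
dosage 1 is exactly 1 and the response at `ED50/100` is exactly 0.5 (50
evenly spaced dosages by default). A zero-baseline Hill curve can realize
this convention only when `(ED50/100)^h < 1/2`; at the boundary the
limiting curve `d^h` is used, and beyond it the pair is rejected loudly
(the pipeline logs and skips such REs). The model curve is normalized the
same way (divided by its value at dosage 1) before computing the mean
squared error, so target and model live on the same scale and the MSE
filter threshold is meaningful. The dosage-to-concentration map is
`α(d) = α_max · d` with `α_max` a fitted parameter.

Optimization is bounded L-BFGS-B over `c ∈ [−0.5, 1]` and log10-scale
`α_max ∈ [1e-2, 1e6]` (and log10 K_D ratio `∈ [1, 1e5]` for mixed fits),
multi-started on a small grid; the two or three best basins are then
polished with Nelder–Mead (relative tolerance 1e-15) and a final bounded
refinement. The polish matters: the (c, K_D-ratio) likelihood surface has
a long, nearly flat trade-off valley, and a looser optimizer can stop at a
visually perfect but biased solution. The lower bound on `c` sits *below*
zero on purpose, so that fits preferring negative competition are
observable — the quality filter (MSE > 0.001, or 0.01 for the two-TF
model, or `c < 0`) then removes them, rather than the bound silently
hiding them. Homotypic fits scan candidate site numbers `n = 1..7` and
report the per-`n` MSE table alongside the chosen fit; mixed fits hold
`n_HA = 3` fixed and take the number of low-affinity sites from the data
(or a fixed value).

## CWM and PWM instance mapping

**Representation.** A contribution weight matrix (CWM) is a signed
4-by-width matrix of per-base attribution scores; a contribution track is
the 4-by-length matrix of such scores over one RE, with the accessibility
summit recorded. Reverse complementation reverses positions and swaps the
A/T and C/G rows; contribution signs are preserved. Coordinates are
0-based half-open and region-relative.

**Similarity.** Windows are scored with a sign-aware continuous Jaccard:
`Σ min(|a|,|b|)·s / Σ max(|a|,|b|)` over all 4·width entries, with
`s = +1` on sign agreement and −1 otherwise; zero-magnitude windows score
0 by convention. The sign convention on negative-contribution windows is
not canonical; it is isolated in one function (`cwm_jaccard`) and fixed by
an oracle test against the naive double-loop definition.

**Thresholds.** A window becomes a candidate instance when its Jaccard
score is at or above the 10th percentile and its total absolute
contribution at or above the 0.5th percentile of all windows scanned for
that CWM — across all tracks and both strands, since the thresholds are
meant as global percentiles, not per-track ones. These permissive defaults
deliberately admit low-affinity instances; the cost is that on
noise-dominated tracks most windows pass, and the subsequent overlap
resolution carries the burden of deduplication. Raising either percentile
can only shrink the instance set (a tested monotonicity).

**Overlap resolution.** Among overlapping candidates the one with the
highest length-weighted score (Jaccard × CWM width) survives — the length
weighting prevents short motifs from winning on score inflation alone.
Ties break toward the lower start, then the lexicographically smaller CWM
id. The same CWM matching the same interval on both strands is collapsed
first, keeping the better-scoring strand and preferring "+" on exact ties
(the true-palindrome case). Output intervals are pairwise non-overlapping
within each region.

**Positional statistics.** Instance midpoints are compared with the RE
summit; instances within ±50 bp (the central 100 bp) are flagged central,
and the buffering-versus-sensitizing positional contrast is tested with a
two-sided Wilcoxon rank-sum test on absolute distances. Location-shuffled
controls are drawn uniformly within the same regions, rejecting placements
that overlap any true instance; if space runs out, fewer controls are
returned with a warning.

**PWM scanning.** Sequences are scanned on both strands with per-position
log-odds scores against a background distribution (motif probabilities are
floored at 1e-4 so absent bases stay finite). The score threshold for a
p-value cutoff (default 0.01, a deliberately permissive value for
low-affinity matching) is derived from the *exact* distribution of the
score under the background model, computed by dynamic programming on an
integer score lattice (granularity 1e-4 log-odds units per step,
per-position rounding). Observed windows are scored on the same lattice,
so reported p-values are exact lattice exceedance probabilities — the test
suite checks DP-versus-exhaustive-enumeration equality for widths up to 8.
The best match per sequence is kept; sequences with no match at the
threshold are reported with score 0, the convention used when match scores
feed downstream predictors. `N` bases contribute score 0.

## What the synthetic data emulate — and what they do not

The generator mirrors the titration design the package targets: five
dosage levels including 0 and 1 (defaults `{0, 0.22, 0.45, 0.75, 1}`; the
intermediate levels of a real degron titration are instrument-determined,
so they are configurable), four biological replicates per level spread
round-robin over two differentiation batches. Expected values follow the
Hill form with per-RE parameters drawn from configurable ranges
(`K ∈ [0.1, 0.9]` dosage units, `h ∈ [1, 4]`, baseline 2–25% of a
log-uniform 50–500 CPM plateau — right-skewed positive values typical of
ATAC CPM at responsive REs). Noise is multiplicative lognormal (replicate
SD 0.1 on the log scale by default) with additive per-(RE, batch) offsets
on the log scale, matching the linear batch correction applied downstream;
outliers are injected as 4–6 SD shifts so the |Z| > 3 filter is exercised
deterministically. Contribution tracks are Gaussian noise plus planted CWM
matrices; sequences are i.i.d. background with consensus or PWM-sampled
insertions.

What this does *not* emulate: count discreteness and
sequencing-depth-dependent noise, correlated noise across REs, fragment
length or transposase-insertion structure in tracks, non-uniform genomic
background composition, or overlapping/clustered real motif grammar.
Passing recovery tests therefore demonstrates estimator correctness under
the stated noise model — not robustness to every pathology of real
ATAC-seq data. Fixed seeds make every synthetic dataset bit-reproducible.

## Problem sizes and defaults in the test and acceptance runs

The test suite runs the noisy ED50-recovery benchmark at 500 REs
(noise SD 0.1), parameter-recovery sweeps at ~10 draws per model class,
CWM recall at 25 tracks × 2 planted instances, and
PWM-enumeration oracles at widths up to 8; these sizes were chosen so each
check is statistically meaningful while the whole suite stays quick enough
to run habitually. The pipeline default caps competition-model refits at
50 REs per run (`n_nmc_fits`), since each polished fit costs a fraction of
a second.

## Known limitations

- The competition model is a single-nucleosome equilibrium; multi-nucleosome
  conformations, remodeler kinetics and out-of-equilibrium effects are out
  of scope.
- The (ED50, h) → target-curve construction cannot represent pairs with
  `(ED50/100)^h ≥ 1/2`; such REs (shallow yet very sensitive fitted
  curves) are excluded from competition-model fitting with a logged count.
- The NMC fit normalizes away the absolute accessibility scale, so `L` is
  not identifiable from a single normalized curve and is fixed rather than
  fitted.
- Percentile thresholds for CWM mapping are relative to the scanned window
  population; on synthetic tracks dominated by noise they are barely
  selective, and downstream analyses should filter on Jaccard score when
  absolute match quality matters.
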