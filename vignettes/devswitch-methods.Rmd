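---
title: "Methods: trend models, age-corrected correlation and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trend models, age-corrected correlation and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devswitch)
```

## The problem

A developmental *switch* is a pair of functionally interchangeable
proteins — typically paralogous receptor subunits — whose usage trades
off over life: one gene's expression rises across development while the
other's falls. On bulk expression cohorts (donors spanning fetal to
late-adult ages, one sample per donor per region) this leaves two
distinct statistical signatures, and `devswitch` separates them:

* the **trend correlation**, the correlation between the two genes'
  fitted population age-trends — strongly negative for a switch; and
* the **age-corrected (residual) correlation**, the correlation of the
  per-subject fluctuations around each trend — a measure of
  subject-to-subject co-regulation that survives after the population
  effect of age is removed.

The distinction matters because the raw correlation of two profiles
confounds them: two genes with mirrored trends have raw ρ close to −1
even when their subjects co-fluctuate positively. Removing fitted
trends and correlating residuals is the nonlinear generalisation of the
partial correlation given age; with a linear trend model the two are
identical (and the package exposes that limit as a test hook:
`age_corrected_correlation(..., degree = 1, n_knots = 0,
age_transform = "linear")`).

## The age axis

All ages live on one internal axis: post-conception days, with birth
fixed at 280 days, 1 month = 30.44 days, 1 year = 365.25 days. The 13
reporting age groups (early fetal EF3 through late adulthood LA15) are
left-closed/right-open intervals on this axis; the printed group table
leaves 38–40 post-conception weeks unassigned (late-fetal ends at 38
PCW, the neonatal group starts at birth), so the late-fetal interval is
extended to birth to make the partition total. Group labels are used
for presentation only, never in the analysis.

Splines are fitted on **log2(age)** by default. Developmental change
concentrates perinatally — the interval from 10 PCW to birth holds as
much regulatory change as the following decades — and the log axis
gives the fetal period the resolution it needs while keeping adult ages
in range. A linear axis is available (`age_transform = "linear"`).

## The trend model

For one gene in one region, with samples sorted by age:

1. **Noise variance.** σ̂² is the mean of the sample variances over a
   sliding (stride-1) window of `window = 10` age-ordered points.
   Windows are computed on the raw values, with no local detrending;
   where the trend is steep this inflates σ̂² upwards. That bias is
   deliberate — σ̂² serves as an upper bound for the spline's MSE, and
   the inflation is what lets a smooth fit through. Profiles shorter
   than the window fall back to a single window (with a warning);
   fewer than 3 points is an error.
2. **Knot search.** Least-squares cubic regression splines with k
   interior knots at the empirical quantiles of the unique transformed
   ages, k = 0, 1, 2, …, up to `max_knots = floor(n/4)`. The selected
   model is the smallest k whose in-sample MSE is strictly below σ̂²
   (an exact fit, MSE < 1e−12, is also accepted so that degenerate
   noiseless profiles terminate). k = 0 is a full cubic polynomial.
3. **Relaxation.** If no k satisfies the bound, it is doubled
   (MSE < 2σ̂², `relaxation = "double_variance"`) and the search
   repeated; `(2σ̂)²` is available as `"double_sd"` since the printed
   form of the rule is ambiguous between the two. If even the relaxed
   bound fails, the max-knot fit is returned; in every relaxed outcome
   the fit carries `relaxed = TRUE`.
4. **Goodness of fit.** Leave-one-sample-out R² refits the model per
   fold — including re-estimating σ̂² and re-selecting k on the n−1
   points — and scores 1 − Σ(yᵢ−ŷᵢ)²/Σ(yᵢ−ȳ)². Values near zero mean
   no detectable trend; negative values indicate overfitting. Boundary
   knots are taken from the full profile's age range so fold
   predictions at the extreme ages stay interpolative; a faster
   fixed-k mode (`refit_selection = FALSE`) is provided but not the
   default.

Numerical notes: duplicate donor ages are handled naturally by least
squares, and knot quantiles are computed on unique ages so knots never
coincide; a knot count whose quantiles collide (or whose basis is rank
deficient) is skipped as equivalent to a smaller k. Quantile-placed
knots are not nested across k, so the MSE sequence can tick up by a
fraction of a percent between adjacent k — the selection rule only
requires crossing the σ̂² bound, not monotonicity. All-equal ages are a
degenerate design and an error, as is a constant profile in LOO R²
(reported as missing).

## The screens

**Trend screen.** Per region, genes with expression range
(max − min, log2) strictly below `min_range = 1.5` are excluded; the
boundary value passes. Surviving pairs get a profile correlation
(Pearson by default; Spearman with midranks available) with two-sided
p-value, and Benjamini–Hochberg q-values computed within the region's
family of tested pairs — the per-region family matches the per-region
reporting of the cross-region heatmaps. A *significant switch* is
q < `alpha = 0.01` with ρ < 0; a two-sided flag is emitted alongside.

**Residual screen.** The same family convention, applied to the
residual correlations after per-gene detrending. When an age window is
supplied (e.g. a prenatal/postnatal split), samples are restricted and
the trends *refitted inside the window* rather than inherited from the
whole-life fit — refitting avoids boundary bias from a curve anchored
by samples outside the window; the whole-life alternative can be
obtained by detrending manually.

**Ranking.** Pairs are ordered by the mean of −log10(q) across regions.
In `rank_pairs()` (raw screen output) only untested cells are excluded
from the mean; in `render_heatmap_table()` the heatmap "gray rule"
applies — a cell is missing when the pair was range-filtered *or* not
significant at α — and the cross-region mean runs over the remaining
cells only, so a pair filtered everywhere drops out of the ranking.

**Candidates.** Pairs form only within pathway elements. Sequence
similarity is the number of identical aligned residues divided by the
length of the *longer raw sequence* (not the alignment length), and the
30% threshold keeps the boundary value. The alignment is true global
Needleman–Wunsch with affine gaps costing 11 + L (end gaps penalised),
delegated to `Biostrings::pairwiseAlignment`; among co-optimal
alignments the reported identity is the one of that implementation's
deterministic traceback — the optimal *score* is unique, and the test
suite checks it against an independently written brute-force
dynamic-programming oracle.

## Null models

* `random_pair_baseline()` draws unordered gene pairs uniformly (no
  self-pairs) and histograms their correlation p-values on the
  −log10 axis; default bins are half-units from 0 to 5 plus an open
  top bin (the exact histogram bins are a presentation choice and are
  configurable).
* `bin_enrichment_test()` compares an observed histogram against
  same-size random redraws, bin by bin, using the add-one permutation
  estimator p = (1 + #{count ≥ observed}) / (B + 1), which can never
  return zero; thresholds finer than 1/(B+1) are rejected as
  unreachable.
* `housekeeping_baseline()` contrasts the fraction of pathway pairs
  and of housekeeping pairs reaching a residual-correlation p below
  10^−θ over a grid of θ — housekeeping genes are expressed but
  developmentally flat, so excess detection there would indicate
  cohort-wide artefacts (RNA quality, cell-composition drift) rather
  than pair-specific co-regulation.
* `subsample_subjects()` draws subjects (not samples) uniformly without
  replacement, defaulting to 53 — the scale of the smaller reference
  cohorts — so correlation p-values from cohorts of different sizes are
  comparable.

All stochastic operations require an explicit seed and run on a private
RNG stream, so results are bit-reproducible and independent of the
caller's RNG state.

## The synthetic cohort

The generator produces the statistical structure the analysis assumes,
with known ground truth:

* **Switch pairs.** y_g(s) = trend_g(age_s) + λ_g·u_s + ε_gs, with a
  shared subject factor u_s ~ N(0, sd_u²) and independent Gaussian
  noise. The implied residual correlation
  λ_a λ_b sd_u² / √((λ_a² sd_u² + σ²)(λ_b² sd_u² + σ²)) is stored as the
  recovery target. Defaults: anti-correlated logistic trends of
  amplitude 3 log2 units (≈ 8-fold, comfortably above the 1.5 range
  filter) centred at birth, λ = 1, sd_u = σ = 0.3 log2 units — typical
  residual scatter for normalised array data — giving a target residual
  correlation of 0.5.
* **Trend shape.** The logistic's slope scale is τ = 1 on the log2-age
  axis, spreading the transition over roughly four log2-age units —
  the perinatal-to-childhood window over which documented subunit
  switches unfold. Markedly sharper transitions are not just
  unrealistic; they defeat the window-based σ̂² rule by hiding
  lack-of-fit below the inflated bound, which contaminates residuals
  with mirrored trend remnants.
* **Background.** Trendless "noise" genes (per-sample sd 1, passing the
  range filter but carrying no subject coupling) and housekeeping-like
  flat genes (sd 0.2, removed by the range filter) round out the
  matrix. Donor ages cover all 13 developmental groups: two per group
  when n ≥ 26, the rest log-uniform over 70–30000 post-conception days.

What the generator does **not** emulate: microarray probe effects,
quantile-normalisation artefacts, RNA-seq count noise, region-to-region
correlation of the latent factors, age-dependent noise variance, or
cell-composition drift. Passing tests therefore certify the statistical
machinery — trend fitting, detrending, calibration of the null
distributions, ranking — on data satisfying the model's assumptions,
not robustness to those real-data complications.

## Problem sizes in the test suite

The packaged checks run at sizes chosen to make their Monte-Carlo
margins comfortable on a single core: 200 random peptide pairs
(length ≤ 25) against the alignment oracle; 50 cohorts of 200 subjects
for sign-reversal recovery; 50 seeds of n = 100 for LOO-R² calibration
(the "strong trend" condition uses noise sd 0.2, i.e. a trend-dominant
profile); 100 replicates of n = 100 for knot parsimony; 1000 pairs for
the FDR null; and 20 runs of 10000 permutations for the enrichment
test's calibration. The demonstration pipeline uses two regions of 200
donors — the scale at which a planted residual correlation of 0.5 is
estimated with standard error ≈ 0.07 and its detection is unambiguous.

## Known limitations

* The knot-count search with the raw-window σ̂² bound underfits
  profiles whose structure is sharp relative to the sampling density;
  the relaxation doubles the bound rather than adapting it.
* A penalised smoothing-spline mode is out of scope; the knot count is
  the only smoothness control.
* The residual correlation inherits Pearson's sensitivity to heavy
  tails (Spearman is available throughout).
* The housekeeping baseline assumes the supplied housekeeping set is
  itself developmentally flat; genes violating that weaken the
  contrast.
* Candidate pairing requires a user-supplied pathway-element table and
  protein FASTA; the package ships only the 17-pathway accession list
  as configuration.
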