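---
title: "Model-based gating of sporulating cultures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based gating of sporulating cultures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporegate)
```

# The biological measurement

A sporulating *Bacillus subtilis* culture contains vegetative cells,
mother cells carrying a developing endospore, and released spores.
Stained with a nucleic-acid dye and run through a cytometer, the three
subpopulations order themselves along two axes: fluorescence (FL1)
drops sharply once the spore coat and cortex block dye uptake, and side
scatter (SSC) rises while the proteinaceous coat assembles inside the
mother cell. Forward scatter separates the populations only weakly.
`sporegate` turns this qualitative picture into reproducible numbers:
the fraction of each subpopulation per sample, tracked across strains,
time points and replicates.

# The processing chain and its assumptions

## Transform

All model fitting happens on asinh-transformed signal areas,
`asinh(x / cofactor)`. For log-normally distributed signals well above
the cofactor this is a log transform (`asinh(x) -> log 2x`), which
makes each subpopulation approximately Gaussian — the assumption every
later stage relies on. The cofactor defaults to 1 (the plain inverse
hyperbolic sine); it matters only when signals approach zero, where
real instruments with additive detector noise typically need values of
150–1000. Because the package cannot know a given instrument's noise
band, the cofactor is exposed and documented rather than guessed.

## Singlet gating

Agglomerates are two or more particles measured as one event. On
height/width channel pairs they betray themselves by an inflated pulse
width at a given height, so the gate fits a robust bivariate normal to
`FSC-H`/`FSC-W` and `SSC-H`/`SSC-W` and removes events that are
Mahalanobis-distance outliers on *any* pair.

The robust fit is the minimum covariance determinant (MCD) estimator:
the mean and covariance of the half-sample (`h = floor((n + d + 1)/2)`)
whose covariance determinant — equivalently, whose covariance-ellipsoid
volume — is minimal. Up to `n − h` arbitrary outliers cannot move it.
Three design choices deserve explanation:

* **Search strategy.** When `choose(n, h)` is at most 5000 the optimal
  subset is found by exhaustive enumeration; otherwise the standard
  fast-MCD recipe runs: 500 random `(d+1)`-point starting subsets, two
  concentration steps each (a C-step replaces the subset with the `h`
  nearest points in Mahalanobis distance and provably never increases
  the determinant), then full C-step convergence for the ten best
  candidates. The test suite checks that this search attains the
  exhaustively enumerated minimum on small instances.
* **Calibration.** The raw covariance of the most concentrated
  half-sample systematically underestimates the population covariance
  (by roughly 3.3× at `h/n = 1/2`, `d = 2`), so the estimate is always
  multiplied by the standard consistency factor
  `alpha / P(chisq[d+2] <= qchisq(alpha, d))`, `alpha = h/n`. Without
  it, a chi-square-based cutoff would silently discard a third of the
  genuine singlets. A further user-facing `scale_factor` multiplier
  (default 1) is kept for compatibility with robust-gating conventions
  that scale the fitted ellipse.
* **Gate-space transform.** The bivariate-normal model is fitted on
  asinh-transformed height/width values (default `pre_transform =
  "asinh"`). Raw pulse signals are log-normal; fitting an ellipse to a
  skewed raw-scale cloud would cut the long tail of perfectly good
  singlets. The monotone transform does not change *which* events have
  anomalous width relative to height — it only makes the inlier cloud
  elliptical, which is the regime the MCD is designed for.

The outlier cutoff defaults to `sqrt(qchisq(0.975, 2)) ≈ 2.716`, the
conventional robust-distance threshold; it is a flag, not a constant.
Two consequences worth knowing: with two (correlated) channel pairs,
expected singlet loss on clean data is bounded by
`1 − 0.975² ≈ 4.9%` and in practice sits near 3% because the two pairs
share the width signal; and since the gate models *one* elliptical
bulk, it assumes the height/width clouds are not split into
well-resolved modes. Heavily multimodal H/W data (populations differing
by many SDs in height) would make the half-sample latch onto a single
mode — a known limitation of MCD-based gates in general.

For tables above `fit_subsample = 10000` events the estimator is fitted
on a random subsample and distances are then computed for all events;
at cytometric sample sizes this changes the estimate negligibly and
keeps the search cost independent of the acquisition size.

## Mixture fitting

Gaussian mixtures are fitted by EM with log-space responsibilities.
Initialization is deterministic: quantile midpoints in one dimension,
a fixed-seed k-means partition (Lloyd, 10 starts; used purely as a
starting point) in higher dimensions — so a fit is reproducible and
row-order invariant. Components use unequal variances (1-D) or full
per-component covariances (d > 1): the most flexible covariance
structure is the single safest choice when the truly best structure is
unknown, at the price of a few more parameters. Convergence is a
relative log-likelihood change below `tol = 1e-8` (cap 1000
iterations); the likelihood trace is recorded and asserted
non-decreasing in the tests. A component whose covariance drops below
`1e-6` of the overall data variance raises a degeneracy error instead
of being silently regularized: a collapsing component almost always
means the data do not support `g` clusters, and the user should know.
Components are reported sorted by ascending first-dimension mean, so in
stain analysis component 1 is the low-signal (LP) and component 2 the
high-signal (HP) population.

## Stain separation and threshold

Stain quality is scored from a univariate two-component fit by the
distance between the fitted means, `mu_diff = mu_HP − mu_LP`, and the
pooled standard deviation, `sigma_pooled = sqrt((sigma_HP² +
sigma_LP²)/2)`; a dye/channel combination separates well when
`mu_diff` is large against `sigma_pooled`. The visual threshold between
the populations is where the fitted component densities cross, found by
`uniroot` on sign-change brackets between the two means. Whether the
densities should carry their mixing weights is genuinely ambiguous in
the field's practice; both are implemented (`weighted = TRUE` by
default, matching the crossover of the mixture's own responsibilities)
and tested against analytic roots. With unequal variances two
crossovers can exist between the means; the one nearest the midpoint is
returned with a warning. The threshold is a QC/visualization aid only —
three-population classification never uses it.

## Classification and label transfer

A `g = 3` mixture on `(asinh SSC-A, asinh FL1-A)` — the two axes that
actually discriminate; FSC can be added by configuration — is fitted
once on a reference sample containing all three populations. Clusters
are named mechanistically: lowest FL1 mean → spore; of the two bright
clusters the higher SSC mean → endospore; remainder → vegetative. Ties
raise a mapping error, and component weights under 2% trigger a QC
warning that the reference may be missing a population.

Every other sample in the experiment set is classified with this one
model (label transfer), by Euclidean distance to the centers (default)
or by maximum posterior. The two rules coincide when populations do not
drift between samples; both are exposed because neither is canonically
"the" right one — the Euclidean rule is insensitive to per-cluster
covariance and weight, which makes it more robust when a sample's
composition differs wildly from the reference (e.g. a late time point
that is 90% spores would otherwise pull posterior assignments toward
the heavy cluster). Ties break to the lowest cluster index,
deterministically.

# The synthetic-data generator

`simulate_culture()` draws per-population counts multinomially, then
per-channel signals as correlated log-normals (`exp(m + s z)`); the
default preset encodes the orderings above — spores dim in FL1,
endospores high in SSC, FSC nearly uninformative — with asinh-scale
pooled-SD separations of ≈5.7 (vegetative–endospore, via SSC-A),
≈12.6 (vegetative–spore) and ≈11.3 (endospore–spore, via FL1-A).
Within a population, area and height of the same scatter signal
correlate at 0.6, and the two width channels — physically the same
transit time seen by two detectors — correlate at 0.9. Heights carry a
larger within-population spread than areas (peak detection is noisier
than integration), so the height/width gating clouds stay unimodal.
Doublets (default 5% of events) are built by summing the area/height
signals of two random singlet draws and inflating widths by 2×, the
standard rationale behind height/width singlet gating. All draws are
seed-deterministic, and truth labels/doublet flags are returned beside
the events (and written as a sidecar CSV by the CLI, never hidden in
the FCS payload).

What the generator deliberately does *not* emulate: detector additive
noise and saturation, spillover/compensation, debris continua, time
drift, and population shape distortions (skewed or censored clusters).
Passing tests therefore demonstrate that the algorithms are correct
under the model's own assumptions — log-normal, well-separated,
ellipsoidal populations — not that any particular instrument's data
meet those assumptions.

# Problem sizes and verification

The test-suite and acceptance-script scenarios use sizes chosen to make
sampling noise negligible relative to the tolerances checked: 2×10³
events for univariate EM recovery (50 simulations), `n = 12, h = 7`
for exhaustive-vs-fast MCD comparisons (all 792 subsets enumerable),
5×10⁴ events for gate operating characteristics, and 20 cultures of
10⁵ events for end-to-end composition recovery, where the multinomial
standard error (≈0.0016) sits far below the ±0.02 acceptance band.
Every expected value asserted in the tests is either a closed form
(pooled SD, analytic crossover roots, asinh identities), an
independently coded brute-force oracle (exhaustive subset enumeration,
Simpson quadrature, permutation matching), or generator ground truth.

# Known limitations

* FCS support is deliberately narrow: list mode, linear-scale
  parameters, float/double/integer data of a common width. Log-amplified
  (`$PnE != 0,0`) or mixed-width integer files are rejected loudly.
* No compensation/spillover handling; the method targets a
  single-stain, two-scatter design.
* Fixed covariance structure rather than information-criterion model
  selection; on borderline data a different structure could fit better.
* The MCD gate assumes one dominant elliptical cloud per channel pair
  (see above).
* Absolute generator constants are synthetic; only the orderings and
  separations are grounded in the biology.
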