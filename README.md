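# sporegate

Automated, operator-independent gating of flow-cytometry data from
sporulating *Bacillus subtilis* cultures.

## The problem

Sporulating *B. subtilis* cultures are mixtures of three subpopulations:
actively growing **vegetative cells**, **endospore-containing mother
cells**, and released dormant **spores**. After staining with a
nucleic-acid dye (SYBR Green), the three separate in cytometric feature
space: spores are dim in fluorescence (FL1) because the coat and cortex
block dye uptake, while the developing coat raises the side scatter
(SSC, granularity) of endospore-containing cells relative to vegetative
ones. Hand-drawn gates around these clouds are subjective and poorly
reproducible between operators; `sporegate` replaces them with fitted
models so that spore formation can be quantified over whole time
courses, strain panels and replicates with no manual intervention.

## The method

For each list-mode sample the pipeline runs:

1. **I/O and subsampling** — FCS 3.0/3.1 files are read into an event
   table; each analysis is evaluated on at most 10⁵ events (uniform
   random subsample).
2. **Transform** — signal areas are brought to near-normal form with the
   inverse hyperbolic sine, x ↦ asinh(x / c) (default cofactor c = 1).
3. **Singlet gating** — agglomerates (doublets) are excluded by fitting
   robust bivariate normal distributions to the FSC-H/FSC-W and
   SSC-H/SSC-W channel pairs with the fast minimum covariance
   determinant (MCD) estimator — the half-sample whose covariance
   determinant is minimal — and flagging events whose Mahalanobis
   distance exceeds √χ²₀.₉₇₅(2) ≈ 2.716 on any pair.
4. **Mixture modelling** — Gaussian mixtures are fitted by
   expectation-maximization. A univariate g = 2 fit on the stained
   channel scores stain quality via the distance between the
   higher- and lower-signal populations,
   μ_HP−LP = μ_HP − μ_LP, and the pooled standard deviation
   σ_HP−LP = √((σ²_HP + σ²_LP)/2); the visual threshold between the
   populations is the root of the difference of the fitted component
   densities.
5. **Classification** — a g = 3 mixture on (asinh SSC-A, asinh FL1-A)
   is fitted once on a reference sample containing all three
   populations; clusters are named by the mechanism above (lowest FL1
   mean → spore; of the remaining two, higher SSC mean → endospore) and
   labels are transferred to every other sample by Euclidean distance
   to the fitted centers (maximum-posterior assignment is also
   available). Per-sample counts and fractions make up the reported
   time course.

A synthetic-data module (`simulate_culture()`, `simulate_timecourse()`)
generates log-normal cytometry events with ground-truth labels and
width-inflated doublets, so the entire pipeline is testable without
instrument data.

## Worked example

```r
library(sporegate)

# simulate a sporulating culture (20% vegetative, 30% endospore, 50% spore)
cfg <- synth_config(n_events = 50000, doublet_rate = 0.05, seed = 42)
sim <- simulate_culture(cfg)

# transform, gate out agglomerates, classify against a reference fit
tb    <- asinh_transform(sim$table, default_transform())
mask  <- exclude_agglomerates(tb, seed = 1)
gated <- subset_events(tb, mask$keep)
ref   <- fit_reference(gated, seed = 1)
labels <- assign_labels(ref, gated)
population_fractions(labels, sample_id = "demo")
```

which prints:

```
<singlet_mask> kept 46001 / 50000 events (92.0%), cutoff 2.716
<reference_classifier> dims = SSC-A x FL1-A, rule = euclidean
  vegetative lambda=0.197 center=(8.9003, 10.492)
  spore      lambda=0.501 center=(9.8914, 7.4929)
  endospore  lambda=0.302 center=(10.288, 10.294)
<population_fractions> demo (n=46001)
  vegetative     9076  (19.7%)
  endospore     13881  (30.2%)
  spore         23044  (50.1%)
```

The gate removed the 5% simulated doublets plus the expected ~2.5% tail
loss per channel pair; the recovered composition (19.7 / 30.2 / 50.1%)
matches the simulated ground truth (20 / 30 / 50%) to well under one
percentage point. `run_stain_qc()` and `run_experiment()` wrap the same
stages for whole sample sheets (strain × time × replicate), writing
tidy `fractions.csv` tables, a serialized classifier and per-stage
event-count logs; `inst/cli/sporegate.R` exposes `simulate`,
`qc-stain` and `classify` subcommands for shell use.

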