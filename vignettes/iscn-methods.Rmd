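---
title: "Individualized structural covariance networks: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized structural covariance networks: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Group-level structural covariance networks correlate regional morphology
across subjects, which yields one network per cohort and no subject-level
statistic. This package implements the individualized alternative: each
subject gets their own weighted network built from how their regional
cortical thickness pattern deviates from a normative control reference.

The construction has three steps, applied to a table of mean cortical
thickness per region (148 Destrieux regions by default):

1. **Within-subject standardization.** A subject's thickness vector is
   z-scored across their own regions. This removes global thickness offsets
   and scale — a uniformly thick or thin cortex is not a network effect —
   leaving only the regional *pattern*.
2. **Normative referencing.** Per region, the mean and sample SD of these
   standardized profiles are computed over the healthy-control group. Every
   subject (patients and controls alike) is then z-scored region-wise
   against this reference, giving a deviation profile `n` with one
   dimensionless entry per region.
3. **Similarity kernel.** The edge weight between regions *i* and *j* is

   `w(i, j) = exp(-(n(i) - n(j))^2)`

   so two regions that deviate from the norm *coherently* (same direction
   and size) are strongly connected (weight 1 in the limit), while
   discordant deviations decay the weight smoothly toward 0. Self-loops are
   excluded (diagonal 0), leaving R(R-1)/2 = 10,878 unique pairs at R = 148.

Both normalization sentences in the method's description are honored by
composing them in this order (within-subject first, then control-referenced).
A `normalization = "single-stage"` switch skips step 1 and references raw
thickness directly; it exists for sensitivity analysis only and is not the
tested default, because raw referencing confounds global thickness with the
regional pattern.

### Assumptions

* Thickness values are positive, in mm, and already region-averaged; no
  imputation is attempted (subjects with missing regions are rejected).
* Controls define the norm. The reference needs at least 2 controls and
  meaningful per-region variance; 32 controls (the default cohort size) is
  small enough that reference noise is a real part of the method's behavior
  (see "The in-sample reference bias" below).
* The kernel is scale-calibrated by the referencing: deviations are in
  normative z units, so weights have an absolute meaning. `exp(-d^2)`
  underflows to exactly 0 only for |d| ≳ 27, far outside anything realistic;
  such entries would be treated as absent edges.

## Graph indices

All indices operate on the weighted, undirected, zero-diagonal matrix; no
thresholding or binarization is applied anywhere.

* **Strength**: per node, the sum of incident weights; globally, the *mean*
  nodal strength. With up to 147 neighbours and sub-unit weights this sits
  in the tens — the scale on which cohort differences of a few units are
  meaningful. (The whole-network edge sum would be two orders larger.)
* **Clustering coefficient** (Onnela variant): per node, the geometric-mean
  intensity of closed triangles on max-normalized weights,
  `C_i = sum_{j,h} (w'_ij w'_ih w'_jh)^(1/3) / (k_i (k_i - 1))`, zero for
  nodes with fewer than two neighbours; globally, the unweighted mean over
  nodes. Among the several weighted clustering conventions this is the
  standard one in the weighted brain-connectivity toolbox lineage; it is
  isolated behind one function so an alternative variant can be swapped in.
* **Path length**: edge lengths are reciprocal weights, `l = 1/w` (strong
  similarity = short edge); all-pairs shortest paths are computed by
  Dijkstra's algorithm from every source (compiled, specialized to the dense
  matrices the kernel produces; cross-checked in the test suite against
  igraph and a Floyd–Warshall oracle). The characteristic path length is the
  mean over ordered finite pairs; a fully disconnected network reports Inf.
  Because kernel weights are strictly positive in practice, the graph is
  complete and the various pair-averaging conventions coincide; averaging
  over *finite* pairs also covers the theoretical underflow edge case.
* **Global efficiency**: mean reciprocal shortest-path length over ordered
  pairs, with disconnected pairs contributing 0. On a complete uniform graph
  of weight w: strength = (R-1)w, clustering = 1, path length = 1/w,
  efficiency = w — these closed forms anchor the test suite.

## Statistics

The statistical stage mirrors how such cohorts are analyzed in practice:

* Per index, a one-way **ANCOVA** (`value ~ covariate + group`, premorbid IQ
  as the default covariate), reporting the group F, p, and partial eta
  squared `SS_group / (SS_group + SS_error)`. With a constant covariate this
  reduces *exactly* to the classical one-way ANOVA, which the tests assert.
  A multivariate Wilks'-lambda pre-test across the four indices is available
  (`manova_pretest()`), but the per-index results are primary: they are what
  per-index F/p/effect-size tables report and what is reproducible.
* **Benjamini–Hochberg FDR** across the family at hand: 4 global indices, or
  the testable nodal regions (zero-variance regions are excluded with a
  warning and the family size reduced accordingly).
* **LSD post-hoc** pairwise comparisons, gated on FDR significance:
  differences of covariate-adjusted means tested against the omnibus model's
  pooled residual mean square and degrees of freedom, unadjusted p values
  (the LSD convention). Verified against `emmeans` in the suite.
* **Partial Pearson correlations** between indices and clinical scores:
  correlation of residuals after regressing both variables on the
  covariates (medication dose and illness duration for patient groups,
  nothing for controls), with the parametric p on n − 2 − k degrees of
  freedom, plus a subject-level **bootstrap** (5000 resamples in the
  analyzed configuration) reporting the percentile 95% interval. The
  percentile method is the minimal-assumption default and is recorded in
  the output; parametric and bootstrap summaries are emitted side by side
  since either may be the one a reader wants to compare against. Resamples
  with degenerate variance are redrawn and counted. All resampling is
  seed-deterministic and leaves the caller's RNG state untouched.

Sample SDs use the n − 1 denominator everywhere, tests are two-tailed, and
α = 0.05.

## The synthetic cohort generator

`simulate_cohort()` generates the statistical structure the analysis
assumes, so the whole pipeline is testable without any imaging data:

* Three groups, by default 39 (schizophrenia-like), 37 (bipolar-like) and 32
  (controls); 148 regions with shared mean thickness drawn uniformly in
  1.5–4.5 mm; a per-subject global scale factor (SD 0.05) emulating overall
  cortical thickness differences; Gaussian per-region noise (SD 0.12 mm,
  a typical between-subject regional variability).
* **Pathology is planted as regional heterogeneity, not uniform thinning**:
  affected regions receive per-subject random offsets. This is deliberate —
  the kernel depends only on pairwise differences of normative z scores, and
  the within-subject standardization removes any uniform shift, so
  increased deviation *spread* is the mechanism by which patient groups can
  show lower strength/clustering/efficiency and higher path length.
  `deviation_sd` is calibrated in normative z units (multiples of the
  per-region control SD). The defaults (0.32 / 0.24 / 0) were chosen once so
  that the simulated group means land on the scale real cohorts report
  (control strength ≈ 66, clustering ≈ 0.33, path length ≈ 2.8, efficiency
  ≈ 0.52), with the bipolar-like group intermediate.
* Covariates (premorbid IQ, medication dose, illness duration) and clinical
  scores (PANSS-positive-like, YMRS-like, verbal fluency, verbal learning)
  are Gaussian with group-specific means on loosely realistic scales. Only
  the correlation machinery, not the clinical values themselves, is under
  test, so no attempt is made to match any published demographic table.
* One named score (default: the YMRS-like score in the bipolar-like group)
  is constructed as `rho * z(index) + sqrt(1 - rho^2) * noise` around the
  named network index (default: nodal clustering of the left superior
  occipital gyrus), so its population correlation with that index is
  `score_effect` (default 0.45). Estimated partial correlations recover it
  with mild attenuation from the covariate adjustment.
* Everything is deterministic given `seed`; the planted ground truth
  (offsets, affected regions, score construction) rides along with the
  cohort object and is exported as JSON by the pipeline.

What the generator does **not** emulate: spatially correlated morphology
(neighbouring regions co-vary in real cortex), non-Gaussian thickness
distributions, site/scanner effects, or any relationship between covariates
and the planted pathology. Passing recovery tests therefore show that the
pipeline detects the planted effect structure at realistic sizes and noise
levels — not that it would behave identically on real MRI-derived tables.

### Effect sizes used in the recovery studies

The replicate studies in the test suite and acceptance script use problem
sizes chosen to finish comfortably on one CPU while keeping the study's
group sizes intact: 100 replicates (tests; 60 in the acceptance script) of
the full 108-subject, 148-region pipeline for the global detection and null
arms, 20 (15) replicates for the nodal recovery arm, and 8 (15) for the
correlation recovery arm. The global arm plants `deviation_sd = 0.8` on 30
random regions in both patient groups. The nodal arm plants
`deviation_sd = 2.5` on the four study regions (left suborbital sulcus,
right superior frontal sulcus, right long insular gyrus and central insular
sulcus, left superior occipital gyrus); 2.5 was fixed a priori as the
magnitude that produces nodal clustering reductions of ≈ 0.15 against a
between-subject SD of ≈ 0.12 — the size of nodal effects this literature
reports — and is large enough for the 148-test FDR family at n = 108.

## The in-sample reference bias

One behavior of the method deserves explicit documentation. The normative
formula scores *every* subject against the mean/SD over all controls — so
each control is scored against a reference that includes itself. In-sample
control deviations then have per-region SD exactly 1 by construction, while
out-of-sample patients drawn from the *same* population have deviation
variance inflated by roughly `(1 + 1/n_c) (n_c - 1)/(n_c - 3)` ≈ 1.10 at
n_c = 32. That inflation alone depresses patient edge weights (≈ 0.02 per
edge, ≈ 2.5 strength units) even when patients and controls are
statistically identical.

Consequences, verified empirically in this package:

* A cohort with **no planted pathology** still shows "patients < controls"
  on strength/clustering/efficiency and "patients > controls" on path
  length in the majority of replicates. A null-calibration check that
  expects ≤ 7% false-positive replicates under the default scoring fails —
  not because the ANCOVA/FDR machinery is broken, but because the
  group-assignment-dependent scoring makes the groups non-exchangeable.
* With `control_scoring = "loo"` (each control scored against the other
  controls, putting both sides out-of-sample) the same null cohorts
  calibrate at the nominal rate (≈ 3–5% of replicates with any
  FDR-significant index), which the suite asserts.
* Detected patient–control differences under the default scoring are
  therefore the sum of any real deviation effect and this reference
  artifact; the two are confounded, and with only 32 controls the artifact
  is not negligible.

The in-sample formula remains the default because it is the method as
defined; `"loo"` is the recommended sensitivity check whenever the control
sample is small.

## Numerical choices and degenerate inputs

* The kernel matrix is symmetrized exactly (`(W + t(W))/2` after the
  elementwise exponential) and validated for symmetry, zero diagonal and
  [0, 1] bounds at every I/O and metric boundary.
* Matrix and cohort TSV round trips are bit-exact (`%.17g` formatting).
* Constant thickness profiles, zero-variance reference regions, constant
  outcomes, rank-deficient ANCOVA designs (covariate collinear with group),
  and insufficient n for partial correlations are all hard errors naming
  the offending entity. Zero-variance *nodal* regions are the one soft
  case: they are excluded from the nodal family with a logged warning,
  since one degenerate region should not abort a 148-region screen.
* Ties in shortest paths are irrelevant to the reported indices (only
  distances are used, not path identities). The pipeline writes no
  timestamps, so identical config + seed reproduces byte-identical output
  trees; partial stage outputs are never reused across runs.

## Known limitations

* The Destrieux registry ships with descriptive English region names; CAT12
  or FreeSurfer exports using `a2009s` codes must be renamed (the `code`
  column of `destrieux_atlas()` provides the mapping).
* The MANOVA pre-test is approximate (Wilks' F approximation) and is not
  gated into the main per-index pathway.
* The bootstrap interval is percentile-only; BCa would need jackknife
  influence values and is not implemented.
* With 32 controls the normative reference itself carries sampling noise;
  nothing in the package corrects for the in-sample bias described above —
  it is surfaced, documented, and made measurable instead.
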