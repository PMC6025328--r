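---
title: "Compositional analysis of soil pollution health-risk screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional analysis of soil pollution health-risk screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilcoda)
library(dplyr)
```

## The problem

Screening-level human health risk assessment of contaminated soils compares
each compound's measured concentration (PEC, μg/kg dry soil) with a
risk-based **soil screening level** (SSL, mg/kg) derived from exposure
assumptions and toxicity criteria. The ratio is the **hazard quotient**
HQ = PEC/SSL, their sum over compounds the **hazard index** HI, and
HI < 1 is read as "no adverse effects expected under this scenario".

`soilcoda` implements that screen for surveys of persistent organic
pollutants (PAHs, PCBs, organochlorine pesticides) and then treats the
vector of *relative contributions* p_i = HQ_i/HI as what it is: a
**composition**. Contributions are positive, sum to one, and carry only
relative information, so ordinary multivariate statistics (correlations,
Euclidean PCA, k-means) are geometrically wrong for them. The package
therefore provides the Aitchison-geometry toolkit — log-ratio transforms,
robust PCA with compositional biplots, principal coordinates on Aitchison
distances, fuzzy c-means on ilr coordinates, and ternary diagrams — so that
the pollution *profile* of each site can be explored independently of the
overall hazard magnitude.

## The risk model

Two SSL equations are implemented, combining incidental soil ingestion,
dermal contact and particulate inhalation for a resident-farmer child
scenario.

Noncarcinogenic (threshold) effects:

$$\mathrm{SSL}^{n}_i=\frac{\mathrm{THQ}\cdot \mathrm{BW_c}\cdot \mathrm{AT_n}}
{\mathrm{EF_r}\,\mathrm{ED_c}\left[\frac{1}{\mathrm{RfD_o}}\frac{\mathrm{IRS_c}}{10^6}
+\frac{1}{\mathrm{RfD_o}}\frac{\mathrm{SA}\cdot \mathrm{AF}\cdot \mathrm{ABS}}{10^6}
+\frac{1}{\mathrm{RfD_i}}\frac{\mathrm{IRA_c}}{\mathrm{VF_s}\ \text{or}\ \mathrm{PEF}}\right]}$$

Carcinogenic (linear, age-adjusted) effects:

$$\mathrm{SSL}^{c}_i=\frac{\mathrm{TR}\cdot \mathrm{AT_c}}
{\mathrm{EF_r}\left[\frac{\mathrm{IFS_{adj}}\cdot \mathrm{CSF_o}}{10^6}
+\frac{\mathrm{SFS_{adj}}\cdot \mathrm{ABS}\cdot \mathrm{CSF_o}}{10^6}
+\frac{\mathrm{InhF_{adj}}\cdot \mathrm{CSF_i}}{\mathrm{VF_s}\ \text{or}\ \mathrm{PEF}}\right]}$$

Scenario defaults (see `noncarc_scenario()` / `carc_scenario()`): THQ = 1,
BW_c = 15 kg, ED_c = 25 y, AT_n = ED×365 d, EF_r = 250 d/y, IRS_c = 100
mg/d, SA = 3470 cm²/d, AF = 0.12 mg/cm², IRA_c = 20 m³/d; TR = 10⁻⁶,
AT_c = 25,550 d, IFS_adj = 100, SFS_adj = 361, InhF_adj = 11. Some modelling
choices deserve a note:

* The noncarcinogenic numerator uses AT_n = ED×365, the averaging time
  defined for threshold effects; the dermal route divides by the *oral*
  reference dose with no gastrointestinal-absorption adjustment, a common
  screening simplification kept here deliberately.
* The dust/vapour dilution term uses the volatilization factor `vf_s` only
  when a compound is flagged volatile, otherwise the particulate emission
  factor (default 1.316×10⁹ m³/kg). All 31 built-in analytes are semi- or
  low-volatile, so the default flag is `FALSE` throughout.
* The contribution vector is defined as p_i = HQ_i/HI, the orientation in
  which the parts sum to one and a compound's share of the summed risk is
  meaningful.
* `basis = "combined"` screens each compound against the *minimum* of its
  two SSLs (conservative); the separate bases remain available.
* Units are fixed by convention: concentrations are stored in μg/kg, SSLs
  in mg/kg, and the 1/1000 conversion lives in `hazard_quotient()` alone.

Toxicity values are *inputs*, not constants. The built-in
`pop_toxicity()` registry is **synthetic**: reference doses are
back-calculated so each compound's noncarcinogenic SSL equals the
reference survey's median concentration divided by its median hazard
quotient, which preserves the published compound risk ranking
(BaP ≫ BbF > BaA > …) and makes the worked examples self-consistent. It
is an emulation for testing and demonstration, not a measured toxicity
database, and real assessments should supply their own registry via
`read_toxicity()`.

## Censored concentrations

Environmental surveys routinely report values "below detection limit".
The package follows the conventional simple-substitution workflow:
`substitute_half_dl()` replaces each censored cell by DL/2 *before* any
summation or log-ratio work, guaranteeing strictly positive data for the
compositional stages. No multiplicative or model-based imputation is
provided by design — the point is to mirror the standard screening
workflow — and the bias this introduces is discussed under *Limitations*.
Per-compound detection limits are not published for the reference survey;
the built-in registry uses each compound's observed minimum as a
surrogate, which is an assumption, flagged as such.

The per-compound summary (`summarize_compounds()`) reports min, median,
max, the **unscaled** median absolute deviation and the censoring
percentage. The MAD is deliberately unscaled (no 1.4826 factor): with
heavy censoring most values sit at one substituted constant and the raw
MAD of such a column is exactly 0, matching how these survey tables are
normally printed. `mad_unscaled(scaled = TRUE)` restores the consistent
estimator if wanted.

## Aitchison geometry

`closure()`, `perturb()`, `comp_power()`, `clr()`, `ilr()`,
`aitchison_dist()`, `variation_matrix()`, `center_composition()`,
`subcomposition()` and `ternary_coords()` implement the standard simplex
operations. The ilr basis is the sequential-binary one,
$z_j=\sqrt{j/(j+1)}\,\ln(g(x_1..x_j)/x_{j+1})$; any orthonormal basis
gives identical distances and identical clr-space results, and the
property tests assert this invariance explicitly. The variation matrix
uses the unbiased (n−1) variance estimator, consistent with the
covariance estimator behind the PCA, so biplot link lengths and variation
entries agree exactly on rank-2 data.

Numerical policy: compositions are validated, never silently clipped —
zeros must be handled upstream by the half-DL step. Closure tolerance is
exact arithmetic (rows are renormalized on entry); round-trip accuracy of
clr/ilr is asserted at 10⁻¹².

## Robust PCA, biplots, PCoA

`coda_pca()` works in ilr coordinates and back-transforms loadings to clr
space. With `robust = TRUE` (default) location and scatter come from the
minimum covariance determinant with subset fraction 0.75
(`MASS::cov.rob`, seeded, hence deterministic; the subset never falls
below p+1 points). The covariance biplot scales clr loadings by the
square roots of the eigenvalues so squared inter-vertex links estimate
log-ratio variances; component signs are canonicalized (largest clr
loading positive). `select_representative()` picks the longest 2-D ray
per compound family (PAH / DDT-and-metabolites / other organochlorines)
to define a ternary subcomposition; ternary plots should use centered
data (`center_composition()`), because a raw BaP-dominated composition
collapses onto a vertex and hides all structure.

`coda_pcoa()` double-centres −d²/2 and scales eigenvectors by
√eigenvalue (Gower), so the full coordinate set reproduces the input
distances; for Aitchison distance matrices negative eigenvalues are
numerical noise and are dropped (with a warning if they are not tiny).
PCoA on Aitchison distances and classical PCA of the ilr coordinates give
the same configuration — the test suite checks both against each other
and against `stats::cmdscale`.

## Fuzzy clustering

`coda_fcm()` is the standard fuzzy c-means (fuzzifier m = 2, tolerance
10⁻⁶ on prototype movement, at most 300 iterations, k-means++-style
seeding) run on ilr coordinates — not clr, whose singular covariance and
redundant dimension distort prototype updates. The objective
Σ u^m d² is recorded per iteration and is non-increasing by
construction; a point coinciding with a prototype receives an indicator
membership. Clusters are relabelled by decreasing membership mass so runs
are reproducible and reports stable. `choose_cluster_count()` reports the
fuzzy partition coefficient and the average silhouette of the hard
labels side by side and flags each criterion's optimum without forcing a
choice when they disagree. Per-cluster profiles are membership-weighted
geometric means of *centered* compositions; on centered data the neutral
profile is 1/D per part, so weights above 1/D mark enrichment.

## What the synthetic generator emulates

`generate_survey()` produces surveys with the structure the analysis
assumes, so the whole pipeline is testable without field data:

* three latent pollution archetypes in contribution space — PAH-dominated
  (the closed reference median-hazard composition, BaP-led), DDT-dominated
  (DDX parts boosted ×250), and mixed organochlorine (PCB/HCH/PeCB/HCB
  parts boosted ×100) — mixed 0.4/0.3/0.3;
* logistic-normal within-archetype variation, σ = 0.35 per ilr
  coordinate. The archetype means are separated by ≥4 within-archetype
  spreads in Aitchison distance (asserted at construction), i.e. the
  clusters are real but overlap-free only in the multivariate sense;
* a log-normal site hazard index with median 0.214 and ~5% of sites above
  HI = 1, echoing the sparse benchmark exceedances such surveys report;
* concentrations obtained by *inverting* the risk model
  (PEC_i = p_i·HI·SSL_i·1000), then left-censored at the registry
  detection limits with DL/2 substitution — censoring applied to
  concentrations, as in the real workflow.

Boosts, σ and the HI parameters were fixed once, from the reference
composition and the separation requirement, when the generator was
designed. Default problem sizes in the tests and the acceptance script —
100 sites × 31 compounds, 20 seeds for the recovery runs, 300 sites for
parameter recovery, 2000–4000 sites for Monte-Carlo rate checks — are the
package's own choices balancing stability against brevity.

What passing tests on this generator do **not** show: real surveys have
spatial autocorrelation, compound-specific measurement error, censoring
that is informative (low-concentration sites are censored more), and
archetypes that are neither Gaussian in ilr space nor as well separated.
Recovery rates on synthetic data are an upper bound on what field data
would yield, and no particular field survey's explained-variance split or
exact cluster memberships can be reproduced without that survey's site
data.

## Limitations

* Half-DL substitution biases rare parts: at n = 300 the per-cluster
  geometric means recover the archetype means to Aitchison distance
  ≈0.16–0.23 on uncensored data, but the mixed-organochlorine archetype
  (whose parts are censored most) drifts to ≈0.28 when censoring at the
  detection-limit surrogates is applied. With heavier censoring,
  model-based imputation would be preferable to substitution.
* The additive hazard index ignores compound interactions, and the screen
  covers three direct exposure routes only (no dietary pathway).
* MCD-based PCA needs n comfortably above the number of parts; with 31
  parts, surveys below ~50 sites should use `robust = FALSE`.

## Reproducing the numbers

Every figure quoted in the README is produced by code in this package:
`scripts/acceptance.R --seed <int> --out <path>` regenerates the worked
screening-level examples, the reference-survey arithmetic, and the
synthetic-survey recovery rates from scratch against the installed
package.
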