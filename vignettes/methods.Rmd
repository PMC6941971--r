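---
title: "From tumour risk factors to drug targets: the sigdecon model and its design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tumour risk factors to drug targets: the sigdecon model and its design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigdecon)
```

`sigdecon` turns clinical and genetic risk factors of a tumour cohort into
landmark-gene mRNA signatures, matches those signatures against a
drug-perturbation expression compendium, and statistically deconvolves the
protein targets whose ligands suppress or enhance each signature. This
vignette explains the model, every tunable that matters, the synthetic data
the package tests itself on, and the design decisions taken where the
problem was genuinely open.

## The signature model

Each cohort $i$ contributes two matrices over the same patients: the disease
data $Y^{(i)}$ ($p_\mathrm{disease} \times n_i$; binary aberrations coded
0/1, continuous scores as given) and row-centred log expression $Z^{(i)}$
restricted to a landmark gene set ($p_\mathrm{genes} \times n_i$, 978 genes
in an L1000-style panel). The disease data are assumed low rank,

$$Y^{(i)} = H^{(i)} F^{(i)} + \varepsilon_Y,$$

and `extract_features()` obtains the rank-$k$ latent features $F^{(i)}$ by
truncated SVD of the standardized disease matrix (continuous factor rows
centred and scaled, binary rows centred only; missing entries are masked
during standardization and then set to the row mean, i.e. zero, so the SVD
sees a complete matrix). The expression data are then regressed onto the
features,

$$Z^{(i)} = B^{(i)} F^{(i)} + \varepsilon_Z, \qquad
\hat B^{(i)} = Z^{(i)} F^{(i)\top} \left(F^{(i)} F^{(i)\top}\right)^{-1},$$

giving the per-gene signature weights $\hat B^{(i)}$
(`fit_signatures()`). The normal equations make the residual rows orthogonal
to every feature row; the unit tests verify this to $10^{-8}$ on random
instances and check $\hat B$ against a pseudo-inverse oracle to $10^{-10}$.

Two conventions make signatures comparable across cohorts of different
size. First, rows of $F$ have unit L2 norm, with the compensating scale
moved into $H$. Second, each feature is oriented so that its
largest-magnitude loading in $H$ is positive.

**Supervised and survival modes.** `supervised_features()` accepts either
user-supplied loadings $H$ (features solved by least squares on the raw $Y$,
since $H$ is expressed in $Y$'s units) or signed marker gene sets (feature =
mean z-scored expression of up-markers minus down-markers).
`cox_risk_feature()` appends the per-patient linear predictor
(log-proportional hazard) of a Cox regression as one extra feature row. The
fit uses a small ridge penalty ($10^{-4}$ by default) for stability and
Efron tie handling; right-censoring is supported, which is what standard
proportional-hazards machinery provides.

## Cross-cohort consistency and sign alignment

Latent features are identified only up to order and sign, so before
comparing or combining cohorts, `signature_consistency()` aligns each
cohort's signature vector to the first cohort (flipping it when their
correlation is negative, and recording the flip) and reports all pairwise
Pearson correlations per feature. A feature passes when its mean pairwise
$r$ exceeds the threshold (default 0.4); only passing features are scored
by the pipeline.

The alignment step is not cosmetic. The match score below multiplies
similarities across cohorts; if one cohort's signature carries the opposite
sign, a drug that suppresses the signature in one cohort appears to enhance
it in another and the product collapses in both directions.
`align_signatures()` applies the recorded flips, and `score_all()` does so
automatically when given a consistency report. Conversely, for *null*
controls the alignment must be switched off (`align_signs = FALSE`): a
signature fitted after shuffling patient labels still contains a
random-signed component of the truth (the shuffled feature retains an
$O(1)$ overlap, since $f^\top P f / \lVert f \rVert$ has unit-scale
variance regardless of $n$), and rectifying those random signs would
manufacture spurious agreement. The package's label-shuffle control
therefore averages *unaligned* consistency over repeated shuffles, which is
centred at zero.

## The perturbation compendium

`pool_replicates()` converts replicate-level profiles into one log2
fold-change profile per (drug, cell line): each plate's mean vehicle (DMSO)
profile is subtracted from that plate's treated profiles, and a drug's
replicates across doses and time points are combined by a
precision-weighted mean (replicate weights inverse to their mean squared
deviation from the replicate mean; plain mean below three replicates). This
plate-wise vehicle-centring plus weighted pooling is the package's
documented stand-in for a full unwanted-variation batch correction; users
with externally pooled profiles can supply them unchanged through the same
compendium container.

`z_transform()` then standardizes each gene to mean 0, population
(ddof = 0) sd 1 across the drugs of each cell line — population sd so that
results are bit-reproducible and the idempotence property is exact.
`filter_cell_lines()` drops lines with fewer than `min_drugs` unique
compounds (default 1000, the coverage filter appropriate for a large public
compendium; synthetic runs set it to 0).

## Match score

With $g_{r,s}$ the z-scored profile of drug $r$ in cell line $s$ and $b$ a
signature vector, similarity is a calibrated, clipped cosine:

$$\sigma(g, b) = \mathrm{clip}\!\left(\frac{\cos(g,b)}{\rho_\mathrm{same}},\ 0,\ 1\right),$$

where $\rho_\mathrm{same}$ is the mean cosine between pairs of drugs
sharing a high-confidence protein target (link score > 900) in that cell
line — so 0 means "no match" and 1 means "a match at the level expected of
two drugs with the same target". Cell lines with fewer than 30 same-target
pairs fall back to the pooled estimate across lines. The form is monotone
in the scalar product $g^\top b$, invariant to positive rescaling of either
argument, and satisfies $\sigma(g,-b) = \sigma(-g,b)$ exactly.

The cross-line consistency weight
$\bar\sigma(r)$ (`drug_consistency()`) is the mean over unordered cell-line
pairs of the clipped cosine between the drug's two profiles divided by
$\rho_\mathrm{cons}$, the compendium-wide mean same-drug cross-line cosine.
Drugs observed in a single line receive the neutral value 0.5 and are
flagged. The match score of drug $r$ for one feature and direction
$\pm$ is

$$S(r) = \bar\sigma(r)\,\frac{1}{N_r}\sum_s w_s
\prod_i \sigma\!\left(g_{r,s},\ \pm \hat B^{(i)}\right),$$

with $N_r = \sum_s w_s$ over the cell lines where the drug is present
(weights default to uniform; user weights let specific cell lines dominate
the search). Direction $-$ scores against the negated signatures and finds
suppressors; $+$ finds enhancers. Every $\sigma$, $\bar\sigma$ and $S$ lies
in $[0,1]$, and the cross-cohort product rewards matches observed in every
cohort.

**Permutation null.** `permutation_null()` permutes the gene labels of the
signature (one fresh permutation per iteration, the same permutation
applied to every cohort, preserving the drug–drug correlation structure of
the compendium), rescores all drugs, and reports per-drug empirical
p-values with the add-one rule $p = (1 + \#\{S^\mathrm{null} \ge S\})/(1 +
n_\mathrm{perm})$ against the drug's own null scores. Because the
signature's entries are exchangeable with their permutations under the
null, these p-values are marginally uniform; note that drugs with strongly
correlated profiles share permutations and therefore produce correlated
p-values, so distribution-level uniformity diagnostics should be run on
compendia without planted clumps of near-identical profiles.

## Target deconvolution

For each protein target, `split_by_target()` divides the compendium drugs
into $R^+$ (linked to the target with confidence strictly above 900 of
1000) and $R^-$ (all other drugs, including sub-threshold links). Targets
with fewer than 4 linked drugs are skipped — too few compounds to support a
distribution-shift test. `ks_one_sided()` then tests whether the $R^+$
scores are shifted toward higher values with the one-sided two-sample
Kolmogorov–Smirnov statistic
$D = \sup_x [\mathrm{ecdf}_{R^-}(x) - \mathrm{ecdf}_{R^+}(x)]$.
The p-value is computed by exhaustive permutation enumeration when
$|R^+| + |R^-| \le 16$ (exact, valid under ties; the switchover is
configurable) and otherwise by the one-sided asymptotic bound
$\exp(-2 D^2 mn/(m+n))$, which is conservative and keeps the false positive
rate at or below nominal.

`enrich_all()` corrects for multiple testing within each (feature,
direction) family using Benjamini–Hochberg by default; a Storey-style
$\hat\pi_0$-scaled variant is available behind `fdr = "storey"`, and
`pool_families = TRUE` corrects across all families jointly. The headline
significance bar is $q < 10^{-4}$. Finally `mst_of_targets()` summarizes
the significant targets as a minimum spanning forest over a protein-link
graph, with link distance $1000 - \mathrm{score}$ and deterministic
lexicographic tie-breaking (Kruskal over a sorted edge list), which removes
redundant links for visualization. `roc_predictions()` evaluates whether
the scores predict the observed direction of signature change after
treatment, sweeping the score threshold and integrating by the trapezoid
rule.

## Synthetic data: what it emulates and what it does not

`simulate_cohorts()` generates the linear-Gaussian structure the model
assumes: shared $B_\mathrm{true}$ (entries standard normal) and
$H_\mathrm{true}$ across cohorts, independent features and noise per
cohort, defaults matching the study conditions (3 cohorts of 200 patients,
16 disease factors, 978 genes, gene noise sd 1, signal scale 1, disease
noise sd 0.5). Each disease factor loads on exactly one latent feature —
risk factors cluster into axes, the way amplification-related and
differentiation-related markers do — with unequal block sizes and
decreasing strengths. This choice is what makes the planted features
identifiable: with dense random loadings, per-factor standardization
compresses the latent strengths toward equality and the SVD mixes the
features arbitrarily. A quarter of the factor rows are dichotomized at
their median to mimic binary clinical variables, spread across blocks so
every axis keeps continuous factors.

`simulate_compendium()` plants one causal target: its drugs (10 of 300 by
default) displace expression along the planted signature by
`effect_size` (default 5) noise-sd units per gene, in every cell line they
appear in; all other drugs are pure noise. The link table assigns causal
drugs to the causal target at score 950, gives each of the 19 decoy targets
the same number of random inert drugs at 950 (testable but null), and adds
random sub-threshold links to exercise the strict-threshold split. Sparse
coverage (each profile present with probability 0.7) is available to
exercise the missing-entry averaging. `simulate_survival()` draws
exponential event times with rate $\exp(X\beta)$ and independent
exponential censoring; `simulate_protrusions()` draws per-image Poisson
counts of exponentially distributed protrusion lengths.

Every generator is a pure function of its arguments and seed (the caller's
RNG state is preserved), and regenerating with the same seed is
bit-identical. What the generators do *not* emulate: real L1000 noise
spectra and probe effects, dose–response structure, the empirical score
distribution of STITCH, correlated clinical covariates, or batch effects.
Passing tests demonstrate that the algorithms do what they claim under the
assumed model — not that the model captures everything in real cohorts.

## Morphology scores

The number of cell protrusions longer than $d$ in an image decays roughly
exponentially, so `fit_protrusion_decay()` builds the survival-count curve
$n(d)$ on 50 equal-width thresholds from 0 to the 99th percentile length
and fits $\log n(d) = \log A - k d$ by least squares over thresholds with
$n(d) \ge 3$. Fitting on log counts keeps the estimate deterministic and
initialization-free; a nonlinear refinement on raw counts is available
behind `refine = TRUE`, started from the log-linear solution. Two derived
scores: the normalized protrusion count $Y_{np} = A / N_{bp}$ (per unit of
cell–background interface) and the morphological differentiation score
$Y_{md} = -1000\,k$ — higher (less negative) $Y_{md}$ means relatively more
long, neurite-like protrusions. Both identities are exact by construction.
Length units (pixels vs µm) are not assumed; the unit is carried as
metadata and scores are unit-dependent. `bootstrap_morphology()` gives
percentile bootstrap intervals (default 1000 resamples over images) per
group and for group differences.

## Numerical choices and degenerate inputs

* `fit_signatures()` refuses a numerically singular $FF^\top$
  (`rcond < 1e-12`) and advises lowering $k$; `extract_features()` errors
  when $k$ exceeds the numerical rank.
* Constant disease-factor rows, zero-norm profiles, all-censored survival,
  plates without vehicle controls, non-decaying protrusion counts and
  sub-minimum sample sizes are all hard errors with named offenders.
* Constant genes within a cell line z-transform to 0 with a warning; a
  compendium-wide nonpositive cross-line cosine makes $\bar\sigma$ fall
  back to neutral with a warning (a wholly null compendium has no
  consistency scale to estimate).
* Duplicate chemical–protein links keep the maximum score with a warning;
  scores outside $[0, 1000]$ are rejected with the line number.
* Tables are written with floats at 6 significant digits, UTF-8, LF line
  endings, in a fixed column order, so byte-identical reproduction is
  meaningful.

## Reproducibility

`run_pipeline()` derives per-stage seeds from a single global seed through
a fixed integer scheme, logs every filtering decision with counts, and
writes a manifest (package version, seed, full configuration, input and
output checksums). `rerun_manifest()` repeats the run and reproduces every
output file byte-for-byte; this is asserted in the test suite at full
problem size. The test suite exercises the statistical guarantees at the
default study conditions (3 cohorts × 200 patients × 978 genes for
signature recovery; 300 drugs × 3 cell lines × 20 targets for end-to-end
target recovery; 40 seeds × 199 permutations for null uniformity; $10^5$
sampled lengths for morphology recovery), sizes chosen so the whole suite
runs in well under two minutes of compute.

## Known limitations

* The exact similarity and consistency normalizations used with real
  public compendia are not derivable from first principles; the calibrated
  clipped cosine is one defensible choice satisfying the documented
  contracts (bounded, zero at no match, one at same-target level, a
  function of the scalar product), and both are isolated behind the
  calibration interface so alternatives can be swapped in.
* $R^-$ contains drugs with sub-threshold links to the target, which
  slightly dilutes contrast for promiscuous targets; this follows the
  strict split definition.
* The Cox feature supports right-censoring only.
* Replicate pooling is a simplified stand-in for factor-based batch
  correction; with heavily batched real data, externally corrected
  profiles should be supplied instead.
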