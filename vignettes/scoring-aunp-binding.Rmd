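---
title: "Descriptor-based scoring of small-molecule binding to monolayer-protected gold nanoparticles"
author: "AuNPScore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor-based scoring of AuNP-analyte binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AuNPScore)
```

## The problem

Thiolate-protected gold nanoparticles (AuNPs) with a ~2 nm core behave as
synthetic nanoreceptors: the self-assembled monolayer of organic ligands
forms transient pockets that bind small organic guests ("analytes") with
measurable association free energies, typically between about −3 and −9
kcal/mol. Measuring or simulating each candidate ligand–analyte combination
is expensive, so a fast surrogate is valuable for screening monolayer
chemistries and guessing which analytes a given particle will capture.

`AuNPScore` implements a deliberately simple surrogate: a linear scoring
function that maps five cheap 2D descriptors of the ligand–analyte pair to a
predicted binding free energy ΔG (kcal/mol). The package provides

* the frozen published model as a citable, checksummed constant,
* the full training/validation protocol used to build such models
  (standardization, ridge regression, nested repeated k-fold
  cross-validation, variance inflation factors),
* Tanimoto-based hierarchical clustering of ligand and analyte chemistry,
* a synthetic dataset generator so every stage is testable end to end.

## The model

Each AuNP–analyte system is a feature vector of five descriptors:

| descriptor | meaning | units / range |
|---|---|---|
| `charge_difference` | absolute difference of ligand and analyte net formal charge at pH 7.4 | elementary charges, ≥ 0 |
| `ligand_logp` | Wildman–Crippen logP of the isolated ligand | dimensionless |
| `analyte_logp` | Wildman–Crippen logP of the analyte | dimensionless |
| `ligand_tanimoto` | Tanimoto similarity of the ligand to a heneicosanethiolate scaffold | \[0, 1\] |
| `analyte_tanimoto` | Tanimoto similarity of the analyte to a phenol scaffold | \[0, 1\] |

The frozen published model is the linear form

ΔG = 0.5450 − 2.5822·ChargeDifference − 0.4023·logP_ligand −
0.4902·logP_analyte − 4.7748·Tanimoto_ligand + 0.6395·Tanimoto_analyte

with ΔG in kcal/mol. It is stored as a constant (`publishedModel()`), not
re-fit at load time: the training set of 32 literature systems is not
redistributable, and the frozen equation is the model's citable artifact.
The JSON serialization carries an md5 checksum over the intercept and
coefficients; `readModel()` refuses a file whose numbers were edited.

```{r}
m <- publishedModel()
m
```

Two coefficient sets are carried. The *unscaled* coefficients apply to raw
feature units and are what `scoreFeatures()` evaluates. The *scaled*
coefficients live in standardized feature space; because the features'
variance inflation factors are all below 3, the magnitude of a scaled
coefficient is a meaningful importance measure, and `rankFeatures()` orders
the descriptors by it (charge difference first, analyte Tanimoto last).

Predictions outside the training range (−8.71 to −2.85 kcal/mol) are
returned unchanged but flagged as extrapolations by `scorePair()`: the model
was trained exclusively on measurable binders and has no information about
non-binders, so no clipping or applicability-domain filter is imposed.

## Descriptor choices

**Fingerprint dialect.** Tanimoto similarity is computed on 1024-bit hashed
linear-path (Daylight-style) topological fingerprints, as produced by
OpenBabel's FP2 fingerprinter (paths of length up to 7 bonds, folded to
1024 bits). Absolute Tanimoto values are *dialect-dependent*: a different
fingerprinter yields different similarities and hence different predictions
through the two Tanimoto terms. For this reason the dialect string is
recorded in every model's provenance, and datasets cache features computed
under a single recorded dialect. Fingerprints are invariant under SMILES
re-notation because every input is canonicalized first.

**Degenerate molecules.** Single atoms and other molecules with no bond
paths can produce an all-zero fingerprint, for which Tanimoto similarity is
0/0. Such inputs are rejected with an explicit error rather than silently
scored 0 or 1.

**Reference scaffolds.** Analytes are compared to phenol (`Oc1ccccc1`),
ligands to heneicosanethiolate (`CCCCCCCCCCCCCCCCCCCCC[S-]`). Both are
configurable in `referenceScaffolds()`. Two notes:

* Ligand SMILES are accepted in thiol or thiolate form and used *as
  given*. The ligand reference is a thiolate, so the protonation notation
  of the input shifts `ligand_tanimoto`; pick one convention per dataset.
* An alternative convention describes *two* user-defined consensus
  reference molecules (a linear alkyl thiol and an aromatic thiol) for the
  ligand similarity. The package does not resolve this ambiguity: the
  single-scaffold defaults above are used, and any other reference can be
  supplied explicitly.

**Charges.** Net formal charges at pH 7.4 are user inputs in the dataset
schema, because robust protonation-state assignment is a hard problem in
its own right. `assignChargeByRules()` offers a transparent convenience:
explicit SMILES charges plus four rules (carboxylic and sulfonic acids
deprotonated; aliphatic amines and amidines protonated), with every
assignment logged for audit. It knows nothing about unusual pKa values.

## Training and validation protocol

`nestedCV()` reproduces the protocol used to build the published model:

1. **Standardization** to zero mean and unit variance, with parameters
   estimated on training rows only (`standardizeFeatures()` takes an
   explicit `fitRows` argument, which is the leakage guard the whole
   protocol rests on). A zero-variance feature on the fit rows is an error.
2. **Ridge regression** in closed form on centered data,
   β = (XᵀX + αI)⁻¹Xᵀy, intercept unpenalized. At α = 0 with a singular
   design a minimum-norm pseudo-inverse solution is returned with a
   warning.
3. **Nested repeated k-fold CV.** Per repeat, systems are shuffled by a
   seeded RNG and split into 5 outer folds. Per outer fold, α is chosen by
   an *inner* 5-fold CV on the training folds only, by grid search over 25
   logarithmically spaced values from 10⁻⁶ to 10⁶ (dense enough that the
   optimum is stable at n = 32; configurable). Ties in inner-CV MSE break
   to the smallest α — the least shrinkage among equals. Out-of-fold
   predictions are collected so every system is predicted exactly once per
   repeat, and metrics (MSE, MAE, RMSE, R²) are computed on out-of-fold
   predictions only, then aggregated across repeats with 2.5/97.5
   percentile confidence intervals (the percentile choice is ours; no
   method is prescribed for these intervals).
4. **Seeding.** One master seed spawns per-repeat seeds deterministically,
   so a `CVResult` is bit-identical on re-run with the same configuration.

Numerical edge case: on very small datasets an inner split can leave a
feature constant in its training rows. Such inner folds carry no
information about α and are skipped; if *every* inner fold is degenerate
the error is raised. The default 5/5 fold structure with n ≥ ~15 never
triggers this.

Two kinds of "final" coefficients can be reported after validation:
per-system mean out-of-fold predictions across repeats
(`meanPrediction()`), and a final full-data fit (`finalFit()`, the default
export, matching common practice). They answer different questions and are
labelled distinctly; `clusterwiseMetrics()` additionally breaks out-of-fold
performance down by a user-supplied cluster label.

`vif()` computes variance inflation factors as the diagonal of the inverse
feature correlation matrix, equivalent to 1/(1 − R²ⱼ) from regressing each
feature on the others; near-singular correlation (rcond < 10⁻¹²) switches
to explicit per-feature regressions and reports infinite VIFs with a
warning.

## Chemical clustering

`pairwiseSimilarity()` builds the full Tanimoto matrix within one role
group (ligands and analytes are clustered separately);
`hierarchicalCluster()` runs agglomerative clustering on the dissimilarity
1 − Tanimoto. **Average linkage (UPGMA) is the default** — the standard
choice for fingerprint dissimilarities, and monotone, so merge heights are
non-decreasing; single, complete and Ward linkage are options and the
method used is recorded in the tree. For fixed input order the
agglomeration is deterministic. The number of flat clusters is a user
parameter of `cutClusters()` — a natural cluster count depends on the
structures at hand and is not hard-coded. Clustering on similarity *to the
reference scaffold* instead of the pairwise matrix is available via
`referenceSimilarities()`. Newick export writes merge heights as
ultrametric branch lengths.

## The synthetic data generator

`generateBindingData()` emulates the *statistical* shape of the training
data, not its chemistry: n = 32 systems by default; charge difference
drawn uniformly from {0, 1, 2, 3} (integer formal charges at pH 7.4);
both logP descriptors uniform on \[−2.1, 2.6\], covering the ligand logP
span reported for the real clusters (−2.07 to 1.61 and up to 2.59);
Tanimoto descriptors uniform on \[0, 1\]; and
ΔG = generating-model prediction + Gaussian noise with sd 0.45 kcal/mol,
matching the published model's dataset-level MAE. The generator returns
the generating truth alongside the data, which is what parameter-recovery
tests compare against.

What it does **not** emulate: correlations between descriptors in real
chemistry (logP and Tanimoto to a hydrophobic scaffold are correlated in
real ligand series; here they are independent), the discrete cluster
structure of real ligand families, or real molecules behind the feature
vectors. Passing recovery tests therefore demonstrates that the estimation
machinery is correct under the model's own assumptions — not that the
five descriptors suffice for any particular chemistry.

`generateMolecules()` is a separate template-grammar generator (substituted
benzenes; alkyl thiolates with varied headgroups) producing parseable
SMILES for exercising the clustering code path on real fingerprints.

## Problem sizes and determinism in the shipped tests

The test suite validates the CV machinery at 4–50 repeats and parameter
recovery over 200 seeded datasets of n = 32 — sizes at which the checks are
sharp (noiseless R² > 0.999; recovered coefficients within 3 standard
errors of truth) while the whole suite stays fast. Production analyses
would use the 1000-repeat default of `cvConfig()`. All stochastic tests fix
their seeds.

## Known limitations

* Predictions inherit the fingerprint-dialect dependence of the Tanimoto
  descriptors; comparing scores across dialects is meaningless.
* The model is linear and static: conformational flexibility, cooperative
  binding and detection-limit censoring are outside its scope, and
  accuracy near the weak-binding end is expectedly poor.
* The charge rules are a convenience, not a pKa engine.
* `chargeDifference` treats charges as exact integers; fractional
  (ensemble-averaged) protonation states are not supported.
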