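---
title: "Quantifying concordance between AlphaFold2 confidence and residue flexibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying concordance between AlphaFold2 confidence and residue flexibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexconcord)
```

## The question this package answers

AlphaFold2 emits two per-residue confidence signals alongside every model:
the pLDDT score (0–100, stored in the PDB B-factor column) and the
predicted aligned error (PAE) matrix, whose entry (x, y) is the expected
positional error (in Å) of residue x when residue y is used for alignment.
Both were designed as accuracy estimates, but they also carry information
about *dynamics*: residues that move a lot in solution are exactly the
residues a single-structure predictor cannot pin down. flexconcord
implements the statistics needed to quantify that correspondence against a
conformational ensemble (an MD trajectory or any multi-model PDB):

* **AF2-score** — the reversed min–max normalization of pLDDT,
  `(pLDDT_max − pLDDT) / (pLDDT_max − pLDDT_min)`, in [0, 1], high =
  flexible, so it points the same way as RMSF.
* **RMSF** — root-mean-square fluctuation of each residue's Cα about its
  mean position after rigid-body (Kabsch) superposition.
* **DV (distance variation)** — `DV(x, y) = IQR over frames of the
  Cα–Cα distance r_xy`. Distances are invariant under rigid motion, so DV
  needs no superposition; it is the trajectory-side analogue of the PAE
  map (symmetric, Å).
* **Concordance statistics** — per-residue Pearson correlation and OLS
  line between score profiles; matrix-level correlation between a
  (symmetrized) PAE map and a DV matrix; near-diagonal band means as a
  disorder signature; cross-protein regression of per-protein mean scores.
* **B-factor bridge** — `B = (8π²/3)·RMSF²` relates crystallographic
  temperature factors to fluctuations; √B is the RMSF-comparable profile
  for experimental structures.

## Superposition protocols

RMSF depends on how frames are aligned, and for multi-domain or partially
disordered proteins this choice dominates the answer.

**Global protocol** (`rmsf_all_atom()`): every frame is fitted on the Cα
atoms of the whole chain to an iteratively refined mean structure — fit
all frames to frame 1, take the mean, refit all frames to that mean,
retake the mean; exactly two iterations, so the procedure is
deterministic. The fit set is the Cα trace even though the protocol is
conventionally called "all-atom" (a single global fit, robust to
sidechain noise).

**Domain-specific protocol** (`rmsf_domain_specific()`): with a
`domain_partition()`, each segment is superposed on its own residues
only, per-segment RMSF is read from the matching fit, and linker residues
between two domains get the arithmetic mean of their RMSF under the two
flanking fits. For a two-domain hinge this is the difference between
reporting ~0 for internally rigid domains (correct) and smearing the
interdomain swing across every residue (what the global fit does).

The Kabsch solver enforces a proper rotation (det = +1) by sign-flipping
the smallest singular direction, errors out on fewer than three or
(nearly) collinear fit points, and returns the transform so callers can
reuse it.

### When superposition-based RMSF is trustworthy

Fitting adds noise of its own: the fitted translation carries variance of
order `mean(σ²)/R` per axis and the fitted rotation of order
`Σ d²σ² / (Σ d²)²` (d = lever arm from the centroid), and both inflate
the apparent fluctuation of the most rigid residues. The estimator is
therefore reliable in the regime where flexibility is *localized* — a
rigid scaffold with mobile loops/termini, which is what per-residue RMSF
profiles of folded proteins look like — and degrades when a large
fraction of the chain is highly mobile (for fully disordered chains no
global superposition is meaningful; that is precisely what the DV matrix
is for, being rigid-motion invariant by construction). The synthetic
defaults below respect this: the Gaussian-chain recovery test uses a
scaffold-plus-loop σ profile, and the package's tests document the noise
floor rather than hiding it.

## Numerical choices

* **Quantiles**: the IQR uses linearly interpolated order statistics with
  plotting positions p(k) = (k−1)/(n−1) (`stats::quantile` type 7, the R
  default). Recorded in every `dv_matrix()` as
  `quantile_method = "linear_type7"`.
* **DCCM**: scalar-product normalization
  `⟨Δr_i·Δr_j⟩ / sqrt(⟨|Δr_i|²⟩⟨|Δr_j|²⟩)` after the global fit-to-mean
  protocol. Residues whose mean squared deviation falls below (10⁻⁶ Å)²
  are numerically immobile; their correlations are set to 0 with a
  warning instead of propagating NaN.
* **PCA**: covariance of mass-weighted (√m-scaled) coordinates with
  1/(F−1) normalization, frames pre-fitted with the global protocol;
  heavy backbone atoms (N, CA, C, O) by default, hydrogens excluded.
  Eigenvalue sum equals the covariance trace (conserved to 1e-8 in the
  tests).
* **PAE symmetrization**: DV is symmetric, PAE is not; the default
  `mean_of_transpose_pair` averages PAE with its transpose before the
  matrix correlation, which is computed over the strict upper triangle
  (no double counting, no forced-zero diagonal). `upper_triangle_raw` is
  available for the raw asymmetric map.
* **p-values** are two-sided from the t transform, floored at 1e-300
  (the conventional "P = 0"), and never thresholded by the package.
* **Degenerate profiles** (constant pLDDT, constant B) normalize to all
  zeros with a warning rather than erroring, so batch pipelines keep
  running.
* **Sign convention**: the AF2-score is an exact order-reversing affine
  image of pLDDT, so `concordance_report()` reports the pLDDT-orientation
  correlation as the exact negation of the AF2-score orientation — the
  two rows can never drift apart numerically.

## The synthetic-ensemble generators

Real MD and AlphaFold2 runs are out of scope; the generators provide
inputs whose correct answers are known in closed form.

* `gaussian_chain()`: an ideal-helix Cα trace plus independent isotropic
  Gaussian displacements of per-residue SD σ_i; expected RMSF is σ_i·√3.
  The mean structure is a helix rather than a straight extended trace
  because a collinear reference leaves the superposition's spin angle
  about the chain axis unconstrained — the degenerate geometry the Kabsch
  routine itself rejects — and the fit then chases the largest-σ
  residues. `sigma_loop_profile()` supplies the canonical σ profile: a
  0.2 Å scaffold with a central loop peaking at 2.0 Å.
* `hinge_two_domain()`: two internally rigid helix segments joined at a
  pivot; per frame the linker and second domain rotate about the hinge
  axis (perpendicular to the helix axis, so the bodies bend coherently)
  by an angle ~ Normal(0, `hinge_angle_std`, default 15°). The truth
  stores the sampled angles and COM geometry, giving a law-of-cosines
  closed form for the interdomain COM distance that tests use without
  touching the rotation code. The construction has a single planted
  collective mode; PCA on it concentrates >80% of the variance in PC1
  (measured ≈0.96 at 15°, the residual being the small-angle sin/cos
  nonlinearity), which is the basis of the locked PC1 threshold of 0.8.
* `disordered_chain()`: every frame an independent freely-jointed chain
  with 3.8 Å steps. Bonded neighbours keep a fixed distance, so the
  near-diagonal DV disorder signature must be read at sequence
  separation ≥ 2 (`near_diagonal_signature(window ≥ 2)`).
* `emulate_plddt()`: `clip(baseline − a(σ − mean σ) + ε, 0, 100)` with
  the gain solved from `a = c·s/(sd(σ)·√(1−c²))` so the expected
  correlation with σ is exactly −coupling; coupling 1 is the
  deterministic map, coupling < 1 with zero noise is rejected as
  unsatisfiable. The default baseline of 60 leaves headroom so realistic
  settings rarely clip.
* `pae_emulator()`: `clip(gain·DV + offset + ε_xy, 0, max_pae)` with
  independent noise per ordered pair — reproducing the asymmetry of real
  PAE maps — and a recorded expected symmetrized correlation
  `g·sd(DV)/√(g²var(DV) + s²/2)`.

All generators draw from their own seeded stream (`withr::with_seed`),
never the global RNG, and are bitwise reproducible. Frames are
statistically independent — unlike real MD there is no autocorrelation — which
is irrelevant for the moment-based estimators here (RMSF, DV, DCCM, PCA)
but means the generators cannot be used to study convergence *rates* of
time-correlated estimators. They also have no sidechains, no excluded
volume, and uniform masses (12.011 amu), so mass-weighted PCA reduces to
uniform weighting on them; passing tests demonstrate estimator
correctness, not force-field realism.

## Problem sizes used in the test suite

The suite and the acceptance script regenerate everything at run time:
RMSF recovery uses R = 100, F = 10 000 (recovery within 5%); hinge
analyses use 30+5+30 residues at F = 150–5000; concordance recovery uses
R = 200 profiles and Fisher-z 95% bands; the disorder-signature
separation uses ten seeds at R = 50, F = 200. These sizes give every
stochastic check a comfortable margin while keeping a full run in the
low minutes on one core.

## Known limitations

* PDB input only (AF2 models and multi-model ensembles); mmCIF and binary
  trajectory formats are not read — convert upstream.
* Structures and trajectories must already be index-matched; there is no
  sequence alignment.
* External disorder predictions (e.g. IUPRED2) are ingested as a TSV
  column, never computed.
* The linker-averaging rule is defined for a linker flanked by exactly
  two segments; linkers at chain termini are rejected.
* `pearson()` requires non-constant inputs; a profile with zero variance
  (e.g. a perfectly rigid trajectory) has no defined correlation and
  errors rather than returning a placeholder.
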