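---
title: "Lesion-wise segmentation evaluation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-wise segmentation evaluation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionqc)
```

This vignette documents the model behind `lesionqc`, the parameters that
matter, the numerical choices made where a definition was genuinely open,
and what the synthetic test data do and do not establish about behavior
on real images.

## The evaluation model

Two binary masks on a common voxel grid are compared in four stages.

**1. Objects.** Each mask is decomposed into maximal connected components
under a chosen adjacency model: 6-connectivity (shared faces) by default
in 3D, with 18 (faces or edges) and 26 (faces, edges or corners)
available; 4/8 in 2D. Coarser adjacency can only merge components, never
split them, so component counts are monotone in the connectivity — a
property the test suite checks on random masks. Which model reflects
biology is genuinely ambiguous (is a pair of diagonal-touching voxels one
lesion seen at coarse resolution, or two?), so connectivity is a
parameter everywhere and no stance is taken. Object volume is
`voxel_count × (spacing_x × spacing_y × spacing_z)`, exactly; nothing
else ever uses world coordinates, because all masks are assumed
pre-registered to the common space (the package refuses, rather than
resamples, when grids disagree).

**2. Correspondence.** An algorithm object and a reference object
correspond when they share at least one voxel. The per-object
description of correspondences (each object's set of overlap partners)
is ambiguous for chained overlaps such as a₁–b₁–a₂, so grouping is
defined as the connected components of the bipartite overlap graph: the
unique maximal closure, and the only one consistent with calling "four
lesions overlapping three lesions" a single split-merge event. Unmatched
objects become singleton groups, so the groups partition every object of
both masks — a conservation law the tests assert on every generated
pair.

**3. Classification.** A group with M algorithm members and N reference
members is classified 1-1 (correct detection / expert agreement), 1-N
(merge), M-1 (split), M-N (split-merge), 0-1 (detection failure /
present only in the reference) or 1-0 (false alarm / present only in the
algorithm). Codes are written algorithm-first. These six classes are
exhaustive; a (0, 0) group is an internal error.

**4. Scores.** The group SDI is `2|Uₐ ∩ U_b| / (|Uₐ| + |U_b|)` on the
unions of the group's member objects; one-sided groups score exactly 0.
Because all intersections lie within groups, the whole-image SDI equals
`2 Σ_g overlap_g / (|A| + |B|)` — the decomposition is checked to 1e-12
in the tests. How to score a *non-1-1* group per lesion is not
standardized anywhere; the group-union SDI used here is this package's
definition, and outputs carry the class code alongside the score so
downstream users can restrict to 1-1 rows if they prefer. A pair of
entirely empty masks has an *undefined* global SDI (`NA`), excluded and
counted in cohort summaries: lesion-free images carry no overlap
information, and substituting 0 or 1 would bias cohort means.

Volume thresholding (`suppress_small`, `threshold_sweep`) retains
objects whose volume is *strictly greater* than the threshold, so a
1 mm³ threshold on a 1 mm isotropic grid removes exactly the single-voxel
lesions; each sweep step re-thresholds the original masks rather than
accumulating.

## Trend curves

Per-lesion SDI against lesion volume is smoothed by local polynomial
regression with tricube weights, implemented directly from the
definition: at each evaluation point, the span-fraction nearest
neighbors in the abscissa get weights `w = (1 − (d/d_max)³)³` and a
weighted least-squares polynomial is evaluated at the point. Keeping the
smoother's hat rows explicit gives the pointwise band from the
linear-smoother variance formula, `se(x₀) = σ̂·‖l(x₀)‖`, with σ̂² the
residual sum of squares over `n − 2·tr(L) + tr(LLᵀ)` approximate degrees
of freedom and a t quantile at that df. The implementation agrees with
`stats::loess(..., surface = "direct")` to better than 1e-6 on random
designs (a test), which is why the latter serves as the independent
oracle rather than a second hand coding.

Choices and defaults:

* **Abscissa**: `log10(volume)`. Lesion volumes span orders of magnitude
  (single voxels to tens of thousands of mm³); on a linear axis the
  span neighborhoods would degenerate at the small end. Configurable.
* **Span 0.75, degree 2**: the long-standing defaults of the tricube
  local-regression tradition; nothing in the method pins them, so they
  are surfaced in every output and in the hybrid model's provenance.
* **Grid**: 100 points equally spaced in log10(volume) over the observed
  range; fitted values are never extrapolated outside it.
* **Degenerate designs**: if the local weighted design is singular (all
  neighbors at one abscissa), the local degree falls back toward a
  weighted mean instead of failing.
* Classes with fewer than `max(degree + 2, 5)` lesions are skipped with
  a warning and listed, not silently dropped.

## Heat maps

The spatial footprint of a class in one evaluation is the union of both
sides' member voxels — the only support rule that gives the one-sided
classes (0-1, 1-0) nonempty, symmetric support; reference-only and
algorithm-only supports are selectable and recorded. Cohort heat maps
are voxelwise means of these binary masks, so values lie on the
`{0, 1/n, …, 1}` lattice and 1 means the class occurs there in every
cohort member. Display thresholding (default 0.15, values at or above
the threshold retained) is a visualization aid, not a statistic. The
axial MIP is the per-(x, y) maximum over the third storage axis.

## Hybrid fusion

`learn_model` fits one correct-detection trend curve per candidate
algorithm, evaluates all curves on a 100-point log-volume grid over
their *common* support, and lets the pointwise argmax define ownership.
Three numerical choices make this deterministic and stable, and all
three are recorded in the model's provenance:

* exact ties go to the lexicographically first algorithm name;
* ownership runs narrower than 3 grid points are absorbed into the wider
  neighbor (argmax chatter from noise would otherwise create spurious
  hairline strata);
* stratum boundaries are the grid midpoints where ownership changes,
  mapped back to mm³; adjacent same-algorithm strata are merged, so
  consecutive strata never repeat an algorithm.

`apply_model` selects, for each stratum `(tᵢ, tᵢ₊₁]` (closed on the
right: a lesion of volume exactly `tᵢ` belongs to the lower stratum),
the owning algorithm's *own* connected components by their *own* volume,
and unions their voxels. Components from different algorithms that
happen to touch are left merged in the output — the fusion is a plain
voxel union — but the event is counted and reported
(`attr(mask, "n_merged")`). Cross-validation is by subject (all
time-points of a subject share a fold) so that no subject contributes to
both the strata it is fused with and their learning.

## Statistics

Per-image SDI values are compared with the two-sided Wilcoxon
signed-rank paired test, delegated to `stats::wilcox.test`: zero
differences are dropped (the classic convention; the method itself is
silent on them), the exact null distribution is used up to 25 untied
nonzero differences, and the normal approximation with tie correction
otherwise — the exact mode is checked against full 2ⁿ sign-assignment
enumeration in the tests. Multiple comparisons default to Holm's
step-down (uniformly more powerful than Bonferroni at the same
family-wise error rate; Bonferroni selectable). Raw and adjusted
p-values are both reported; the α level is the caller's choice. Cohort
confidence intervals for mean SDI use the normal approximation
`mean ± z·SD/√n` — no method is pinned by the underlying analysis, so
this is an explicit package choice, exposed via the `level` argument.

## The synthetic generator

The generator exists so every result above is testable without any image
download, and its defaults *are* the test-bench conditions:

* **Pairs** (`pair_spec`): 48³ grid at 1 mm isotropic, lesion volumes
  log-uniform on 2–200 mm³, a composition of 4 correct detections, one
  merge, one split, one split-merge and two disagreement lesions per
  side, and a 1-1 target SDI of 0.65 — the level typical of expert
  boundary agreement. Groups are axis-aligned boxes placed with ≥ 2
  empty voxels between groups (no unintended adjacency under any
  connectivity model); split/merge groups carve one box into sub-boxes
  separated by 1-voxel gaps, so every piece still overlaps the other
  side but the pieces are 6-disconnected.
* **Ensembles** (`ensemble_spec`): 20 subjects × 4 time-points × 5
  lesions (400 lesions) on 32³ grids, volumes log-uniform on 10–250 mm³,
  two algorithms with a designed performance crossover at 50 mm³ (mean
  SDI 0.8 below vs 0.4 above for A1, reversed for A2) and Gaussian SDI
  noise of SD 0.05. A rendition at target SDI p keeps the first
  `o = round(pV/(2 − p))` scan-order voxels of the reference lesion, so
  the realized SDI `2o/(V + o)` matches the target to within 1/V —
  quantization the calibration tests account for. False alarms
  (separated extra boxes) and detection failures (dropped renditions)
  are injected at configurable rates, zero by default.

What this emulates: controlled counts per detection class, controlled
volume distributions, controlled per-algorithm SDI-versus-volume
profiles, and subject/time-point cohort structure. What it deliberately
does not emulate: lesion morphology (boxes, not blobs), spatial anatomy
(placement is uniform, so heat maps have no anatomical structure),
intensity or texture, rater-specific biases, and registration error.
Tests passing on this bench therefore establish the *accounting* —
classification, conservation, calibration, threshold and fusion
logic — not segmentation performance on clinical images.

## Problem sizes and determinism

The shipped tests run the oracle-equivalence loop on 100 random 15³–20³
mask pairs across all three connectivities, taxonomy conservation on ten
generated pairs, LOESS checks at n = 200, band coverage over 300
replicates, and the full 400-lesion crossover ensemble for hybrid
recovery — sizes chosen to exercise every code path while keeping the
suite fast enough to run habitually. Every stochastic step is seeded:
generators take a seed in their spec and restore the caller's RNG state,
so the same spec always yields the same masks, and `apply_model` is
deterministic given a model and masks.

## Limitations

* The per-lesion SDI for non-1-1 groups is this package's group-union
  definition; comparisons with tools that score only 1-1 pairs should
  restrict to that class.
* LOESS span/degree and the confidence-band construction are declared
  defaults, not fitted; trend shapes at the extreme volume ends sit on
  few neighbors and inherit the usual edge variance of local regression.
* The hybrid learner assumes the candidates' correct-detection curves
  cross cleanly; with strongly overlapping noisy curves the minimum
  stratum width trades resolution for stability.
* Only binary masks are supported — no probabilistic or fuzzy overlap,
  no longitudinal lesion tracking, and no anatomical-region reporting.
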