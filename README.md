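# lesionqc

Lesion-wise evaluation of binary segmentations with a refined
Sørensen-Dice analysis.

## The problem

The Sørensen-Dice index,

```
SDI(A, B) = 2 |A ∩ B| / (|A| + |B|),
```

is the standard agreement score for medical image segmentation. It works
well when the number of objects is known (one liver, two hippocampi), but
for problems such as white matter lesion segmentation in multiple
sclerosis — where an image may contain anywhere from zero to hundreds of
lesions — a single global SDI conflates two different questions: *were
the lesions detected at all*, and *how well were their boundaries drawn*?
A global score of 0.6 cannot distinguish an algorithm that misses every
small lesion from one that finds them all but draws generous boundaries.

`lesionqc` refines the analysis to the level of individual lesions. Each
segmentation is decomposed into connected components (6-connectivity by
default; 18 and 26 available for sensitivity analyses), components of the
two segmentations are matched through voxel overlap, and every maximal
group of mutually overlapping objects is classified into a six-class
detection taxonomy:

| code | algorithm vs. manual | manual vs. manual |
|------|----------------------|-------------------|
| 1-1  | Correct Detection    | Expert Agreement  |
| 1-N  | Merge                | Ambiguous Masks   |
| M-1  | Split                | Ambiguous Masks   |
| M-N  | Split-Merge          | Ambiguous Masks   |
| 0-1  | Detection Failure    | Expert Disagreement |
| 1-0  | False Alarm          | Expert Disagreement |

Each group gets its own SDI (computed on the union of its members per
side), so agreement can be examined per lesion, against lesion volume
(LOESS trend curves with confidence bands), across volume thresholds
(how much disagreement is due to tiny lesions?), and spatially (cohort
heat maps of where each class occurs).

On top of the per-class trends, the package implements a **hybrid fusion
algorithm**: given several candidate segmentations of the same images, it
learns the lesion-volume strata in which each candidate has the highest
correct-detection SDI, then fuses held-out segmentations as

```
H = ∪ᵢ { l ∈ A₍ᵢ₊₁₎ | tᵢ < vol(l) ≤ tᵢ₊₁ },
```

i.e. the union over strata of the owning algorithm's own lesions, with
strata learned by subject-level cross-validation.

## A worked example

Everything below is reproducible without any data download: the package
ships a synthetic generator that places box-shaped lesions with an exact,
known detection-class composition.

```r
library(lesionqc)

gp <- generate_pair(pair_spec(seed = 7))   # masks + ground truth
ev <- evaluate_pair(gp$side_a, gp$side_b)  # side_a = algorithm, side_b = reference
summary(ev)
#> Lesion-wise segmentation evaluation (side_a-vs-side_b)
#>   connectivity: 6   volume threshold: 0 mm^3
#>   global SDI: 0.4601
#>   match groups: 11
#>
#> Detection classes (groups = lesion events):
#>  class count percentage
#>    1-1     4      36.36
#>    1-N     1       9.09
#>    M-1     1       9.09
#>    M-N     1       9.09
#>    0-1     2      18.18
#>    1-0     2      18.18
#>
#> Correct-detection (1-1) group SDI: mean 0.6566 over 4 lesion(s)
```

The global SDI of 0.46 looks poor, but the refined view shows why: the
four correctly detected lesions agree at SDI ≈ 0.66 (for context, an SDI
of 2/3 means the two masks disagree on half of the union's voxels), and
the score is dragged down by four disagreement lesions that one side did
not see at all. A volume-threshold sweep shows how much of that is small
lesions:

```r
threshold_sweep(gp$side_a, gp$side_b, c(0, 1, 10))
#>   threshold_mm3 global_sdi n_groups n_0_1 n_1_0
#> 1             0  0.4601156       11     2     2
#> 2             1  0.4601156       11     2     2
#> 3            10  0.4083225        8     3     2
```

Hybrid fusion on a two-algorithm ensemble with a designed performance
crossover at 50 mm³ (A1 better below, A2 better above):

```r
en <- generate_ensemble(ensemble_spec(seed = 11))
cv <- cross_validate(en$algorithms, en$reference, en$image_subjects, folds = 2)
cv
#> Cross-validated hybrid fusion over 80 image(s), 2 fold(s)
#>   fused SDI: mean 0.7497 (SD 0.0754), range [0.5210, 0.8720]
#>   A1:          mean 0.5344
#>   A2:          mean 0.7021
cv$models[["1"]]
#> Hybrid fusion model: 2 volume strata
#>   (0, 59.34] mm^3  ->  A1
#>   (59.34, Inf] mm^3  ->  A2
#>   LOESS span 0.75, degree 2; 100-point grid
```

The learned threshold (59.3 mm³) recovers the designed crossover, and the
fused segmentation beats both ingredients.

Real data enters through NIfTI masks: `read_mask("seg.nii.gz", space_tag
= "MNI")`, then the same functions. `run_evaluate()` and `run_cohort()`
write full report sets (CSV tables, JSON summaries, heat-map NIfTIs and
figures); the same workflows are reachable from a shell via
`exec/lesionqc` (`evaluate`, `sweep`, `cohort`, `simulate-pair`,
`simulate-ensemble`).

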