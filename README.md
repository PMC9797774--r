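# strokescore

Evaluation and data-handling toolkit for two-stage stroke CT segmentation
challenges. Stage 1 is an image-level stroke present/absent classification
gated by an F1 threshold; stage 2 asks teams to segment ischemic (label 1)
and hemorrhagic (label 2) lesions, scored with a boundary-tolerant
intersection-over-union and aggregated into a rank-to-points leaderboard.
The package is for challenge organizers, and for anyone who wants to score
their own segmentations the way such a competition would.

Because lesion boundaries on non-contrast CT cannot be drawn with perfect
precision even by expert radiologists, the metric compares a prediction
`P` against morphological *envelopes* of the ground truth rather than the
truth itself. Each class of the truth is eroded and dilated with a 3×3
all-ones kernel (one iteration) and merged back class-preservingly into an
eroded envelope `E` and a dilated envelope `D`; then

```
IoU(G, P) = #{ (i,j) : D[i,j] = P[i,j] ≠ 0 } / #{ (i,j) : E[i,j] ≠ 0  or  P[i,j] ≠ 0 }
```

so any prediction lying between `E` and `D` with matching classes scores
exactly 1 — a one-pixel boundary disagreement is free. Per image, the team
with the highest IoU gets `n_teams` points, the next `n_teams − 1`, and so
on; all teams with IoU 0 get one point less than the worst positive team;
totals are sums over images (36 teams × 97 images: maximum 3492, minimum
positive 97).

Alongside the metric the package provides: the stage-1 CSV gate, the
four-folder dataset layout (`DICOM`/`PNG`/`MASK`/`OVERLAY`) with a literal
0/1/2 mask-PNG codec and overlay renderer, a whitelist-based DICOM
anonymizer with a minimal built-in Explicit-VR-Little-Endian codec, the
ICD-10/procedure-code ± 15-day registry cohort filter, seeded synthetic
generators (lesion phantoms, degraded submissions, DICOM files, case
registries), and a command-line script tying it together.

## Worked example

```r
library(strokescore)

# a 128x128 phantom with one ischemic and one hemorrhagic lesion
gt <- gen_phantom(rows = 128, cols = 128, n_class1 = 1, n_class2 = 1,
                  radius_range = c(8, 16), min_gap = 3, seed = 42)

pred_good <- degrade(gt, degradation_spec(dilate_steps = 1))      # one step too large
pred_off  <- degrade(gt, degradation_spec(shift = c(5L, 5L)))     # misplaced
pred_miss <- degrade(gt, degradation_spec(drop_lesion_prob = 1))  # found nothing

c(good = relaxed_iou(gt, pred_good),
  off  = relaxed_iou(gt, pred_off),
  miss = relaxed_iou(gt, pred_miss))
#>      good       off      miss
#> 1.0000000 0.6163683 0.0000000
```

The one-step-dilated prediction stays inside the tolerance envelope and
scores a full 1.0; the 5-pixel-shifted one loses the pixels that leave the
dilated envelope; the empty one scores 0.

```r
iou <- rbind(alpha = c(1.00, 0.92), beta = c(0.81, 0.95), gamma = c(0, 0.40))
colnames(iou) <- c("img001", "img002")
board <- score_leaderboard(iou)
board$points
#>       img001 img002
#> alpha      3      2
#> beta       2      3
#> gamma      1      1
board$totals
#> alpha  beta gamma
#>     5     5     2
```

On `img001`, `gamma` scored 0 and receives one point less than the worst
positive team. The stage-1 gate works the same way from named 0/1 vectors
or CSVs:

```r
res <- stage1_evaluate(truth = c(a = 1L, b = 1L, c = 0L, d = 0L),
                       submission = c(a = 1L, b = 0L, c = 0L, d = 0L))
res$f1         #> 0.6666667
res$qualified  #> FALSE  (threshold 0.75)
```

The command-line interface (installed at
`system.file("cli", "strokescore", package = "strokescore")`) exposes
`stage1`, `stage2`, `make-fixtures`, `anonymize`, `render-overlay` and
`filter-registry` subcommands over the same functions.

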