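---
title: "Boundary-tolerant IoU scoring for two-stage stroke CT challenges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary-tolerant IoU scoring for two-stage stroke CT challenges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokescore)
```

## The problem

Segmentation challenges on non-contrast head CT ask teams to delineate
ischemic and hemorrhagic stroke lesions. Lesion boundaries on CT are
genuinely ambiguous — even expert radiologists will not draw the same
contour twice — so a scoring metric that compares predictions against a
single reference contour pixel-for-pixel punishes teams for disagreements
that no reader could adjudicate. This package implements the full
evaluation machinery of such a two-stage competition: an image-level F1
qualification gate (stage 1), a boundary-tolerant multi-class
intersection-over-union metric and a rank-to-points leaderboard (stage 2),
the dataset layout and DICOM anonymization used to distribute the images,
the registry filter used to screen candidate cases, and seeded synthetic
generators so every component can be exercised without clinical data.

## Label masks and the tolerance envelope

Ground truth and predictions are integer matrices with pixel values
0 (background), 1 (ischemic) and 2 (hemorrhagic). To build the tolerance
band, the ground truth is split into its two class-restricted binary views;
each view is eroded and dilated with a 3×3 all-ones structuring element,
one iteration, with pixels outside the grid treated as 0 (zero padding);
and the per-class results are merged back into label masks so that pixel
classes are preserved. Where the two classes meet after dilation, class 2
overwrites class 1 — a fixed, documented precedence, chosen because the
scoring procedure applies the class-2 assignment last. The result is a pair
`(eroded, dilated)` bracketing the truth:

```{r}
gt <- matrix(0L, 9, 9); gt[3:7, 3:7] <- 1L
env <- build_envelope(gt)
sum(env$eroded != 0); sum(gt != 0); sum(env$dilated != 0)
```

## The relaxed IoU

With `E` and `D` the eroded and dilated envelopes and `P` the prediction,

$$\mathrm{IoU}(G, P) \;=\;
\frac{\#\{(i,j) : D_{ij} = P_{ij} \neq 0\}}
     {\#\{(i,j) : E_{ij} \neq 0 \ \lor\ P_{ij} \neq 0\}}.$$

The intersection is counted against the *dilated* truth — a predicted pixel
is correct if it matches the dilated envelope's class — while the union is
counted against the *eroded* truth, so uncertain boundary pixels of the
reference do not enlarge the denominator. Consequently any prediction whose
support lies between the two envelopes, with classes matching the dilated
envelope, scores exactly 1: a one-pixel boundary error in either direction
is free.

```{r}
pred <- matrix(0L, 9, 9); pred[3:7, 4:8] <- 1L  # shifted right by one
relaxed_iou(gt, pred)
```

Numerical edge cases are fixed deterministically:

* **Empty union** (possible only when erosion removes the truth entirely —
  thin lesions — *and* the prediction is empty): both parties assert
  "nothing confidently present", the score is defined as 1 and a warning is
  emitted.
* **Class labels in the merged envelopes.** The per-class erosions and
  dilations are merged back with their own class labels (1 and 2), not
  collapsed to binary; otherwise the intersection test would be vacuous for
  hemorrhagic pixels. Class-preserving merging is what the procedure's
  prose requires, and the comparison against predictions with values
  {0,1,2} only makes sense this way.
* **Cross-class adjacency.** Because class 2 wins the merge, a class-2
  lesion touching class-1 support overwrites the class-1 labels on the
  contact band of the dilated envelope — so there a *pixel-perfect*
  prediction scores slightly below 1. This is a real property of the
  metric, asserted in the test suite, and worth knowing when interpreting
  scores on images containing both lesion types side by side.

## Stage 1: the F1 gate

Teams classify every image as stroke present (1) or absent (0) and submit a
CSV (`image_id,label`). With "present" as the positive class,
`F1 = 2PR/(P+R)`; teams below the threshold (default 0.75) are eliminated.
Zero denominators (no predicted positives or no true positives) yield an F1
of 0, the standard convention. Submissions must cover exactly the truth's
image ids; mismatches are reported by id.

## Stage 2: rank-to-points aggregation

Per image, teams are sorted by decreasing IoU. With `n` teams, the best
receives `n` points, the next `n − 1`, and so on; all teams with an IoU of
exactly 0 receive one point less than the lowest-ranked team with positive
IoU. Totals are per-team sums over images, so with 36 teams and 97 images a
team ranked first everywhere totals 36 × 97 = 3492 and a team always last
among the positive scores totals 97. On an image where exactly 10 of 36
teams have positive IoU, those ten receive 36…27 and each of the other 26
receives 26.

Two situations the rule leaves open are fixed as documented conventions,
not recovered facts:

* **Exact ties** among positive IoUs share the best position's points
  (competition-style "1224" ranking) and counting continues after the tie
  block — a tie never penalizes a team. Equality means exact floating-point
  equality; no rounding is applied before ranking.
* **An image where no team scores above 0** awards 0 points to everyone:
  the reference team ("lowest IoU greater than 0") does not exist, and 0 is
  the least surprising extension.

```{r}
rank_points(c(a = 0.9, b = 0.9, c = 0.5, d = 0, e = 0))
```

## Dataset layout, mask codec, anonymization

Each image id yields four files: `DICOM/{id}.dcm` (anonymized 16-bit
single-frame CT), `PNG/{id}.png` (display rendering), `MASK/{id}.png`
(single-channel 8-bit PNG storing the literal values 0/1/2 — a label image,
not a picture) and `OVERLAY/{id}.png` (display image with lesion interiors
blended at alpha 0.4 and boundaries drawn opaque: blue for ischemic, green
for hemorrhagic; a boundary pixel is a lesion pixel with a 4-connected
neighbor of different label). The display rendering applies the DICOM
rescale slope/intercept and then linear window leveling from each file's
WindowCenter/WindowWidth tags; a fixed brain window would be an
alternative, but per-file tags reproduce what a viewer would show for that
file.

Anonymization is whitelist-based: every tag is removed except 20 technical
tags (geometry, bit depth, rescale and window parameters, pixel data) —
see `anonymization_profile()`. Three structural file-meta elements outside
the whitelist (FileMetaInformationVersion, MediaStorageSOPClassUID,
ImplementationClassUID) are retained because the container is unreadable
without them; this deliberate divergence is confined to group-0002
plumbing and carries no patient information. Pixel data passes through
byte-identical. The DICOM codec itself is a minimal in-package
implementation of the Explicit-VR-Little-Endian single-frame profile
(sequences are rejected); generated files are cross-checked against an
independent parser in the test suite.

## Registry filtering

Candidate cases are screened from a coded registry by three criteria, each
read as *A and (B or C)*: a stroke ICD-10 diagnosis confirmed by head CT or
diffusion MRI; a thrombectomy anchored the same way; and endovascular
aneurysm treatment confirmed by head CT. The two legs must fall within
±15 days of each other, inclusive at the boundary (the source states the
window without boundary semantics; inclusive is the deterministic choice).
The grouping *(A and B) or C* is deliberately not offered: it would select
every diffusion-MRI case regardless of diagnosis, contradicting the
screening purpose. Free-text report screening is a case-insensitive,
whitespace-normalized substring search for the three "normal study"
phrases — not sentence parsing; the original reports were in another
language and their retrieval machinery is not reproducible.

## Synthetic generators

All fixtures are generated in code, deterministically per seed (R's
Mersenne-Twister behind `withr::with_seed`, leaving the caller's RNG state
untouched):

* `gen_phantom()` places random rotated elliptical blobs of each class in
  a 512×512 grid by default (tests and the acceptance workload use 128×128
  or smaller; the construction is size-invariant, and 128×128 keeps the
  full 36-team × 97-image scoring run under a minute). The optional
  `min_gap` keeps class-2 lesions at a Chebyshev distance from class-1
  support for fixtures whose premise requires non-interacting lesions (see
  the adjacency note above). Phantoms emulate the *format* of the data —
  multi-class blob masks — not CT anatomy, texture, scanner noise, or
  reader variability; passing tests say the scoring machinery is correct,
  not that any model performs well on real CT.
* `degrade()` turns a truth into a controlled-quality prediction:
  per-lesion drops and class flips, per-class morphological growth or
  shrinkage, and translation. An identity spec is the identity; a one-step
  dilation or erosion stays inside the envelope and still scores 1.
* `gen_dicom()` emits a parsable 16-bit CT slice carrying the whole
  anonymization whitelist (12-bit pixel depth, brain window 40/80, rescale
  intercept −1024) plus any requested identifying tags with synthetic
  values.
* `gen_registry()` plants records that match each filter criterion and
  keyword the requested number of times and fills the rest with noise
  engineered to match nothing (lone diagnoses, imaging outside every
  window, out-of-vocabulary codes).

## Reproducing the published scoring facts

`scripts/acceptance.R` regenerates, from scratch, a 36-team × 97-image
competition in which one team is strictly first and one strictly
last-positive on every image, by constructing per-team predictions nested
inside the eroded ground-truth support (so team *k*'s IoU is
(|E|−k+1)/|E| — distinct, positive and strictly ordered by construction),
scoring every mask pair with `relaxed_iou()` and aggregating with
`rank_points()`. The totals of the designated teams and the points of the
zero-IoU teams on a 10-of-36 image are written as JSON. The same
construction is asserted in the test suite.

## Limitations

* The codec supports exactly the distributed profile (flat Explicit VR
  Little Endian, single frame); it is not a general DICOM implementation.
* Tie-breaking among equal IoUs and the all-zero-image rule are documented
  conventions; the original implementation's behavior in those cases is
  unknown, as is its class precedence on envelope overlap.
* Real competition outcomes (per-team score distributions, the top-3 mean
  IoU) depend on the original submissions and are out of scope; nothing
  here estimates them.
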