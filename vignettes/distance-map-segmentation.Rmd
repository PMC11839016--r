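---
title: "Distance-map regression for cell instance segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-map regression for cell instance segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celldist)
```

## The model

`celldist` treats instance segmentation of cultured cells as a
regression problem. The target for a frame with instance labels
$L : \Omega \to \{0, 1, \dots, N\}$ is the per-cell normalized distance
map

$$
D(p) \;=\;
\begin{cases}
\dfrac{d\!\left(p,\; \Omega \setminus C_{L(p)}\right)}
      {\max_{q \in C_{L(p)}} d\!\left(q,\; \Omega \setminus C_{L(p)}\right)}
  & L(p) > 0 \\[4pt]
0 & L(p) = 0,
\end{cases}
$$

where $C_k$ is the pixel set of cell $k$ and $d$ is the Euclidean
distance to the nearest pixel *not in that cell* — background, any other
cell, or out of frame all count as non-cell. Three consequences shape
everything downstream:

* the map's support equals the mask's support exactly (a boundary cell
  pixel has raw distance 1, never 0);
* every cell attains the value 1 at its core, regardless of size, so one
  fixed pair of thresholds works across cell sizes;
* two touching cells are separated by a valley even when the image shows
  no edge between them, because each cell is encoded against its own
  boundary.

The assumption being bought is geometric: each cell must have a single
well-defined core. Peanut-shaped (nearly dividing) cells violate it —
their map looks like two disjoint cells and they are over-split. This is
a documented limitation, not corrected here; the synthetic generator
avoids such shapes by construction so that round-trip tests measure
pipeline correctness rather than this known failure mode.

### Instance recovery

Recovery applies two strict thresholds to a predicted map: the *binary
mask* $D > 0.05$ and the *cell centers* $D > 0.5$. The 8-connected
components of the centers image seed a marker-controlled watershed that
floods the negated map (highest values first) restricted to the binary
mask. Basins meeting define the recovered boundaries; every flooded
foreground pixel is assigned to a basin (no unlabeled ridge pixels), and
foreground components containing no seed are discarded — a region
without a confident core is noise, not a cell. Both threshold values are
global constants of the method, shared by the library functions and the
command-line wrapper; they are deliberately *not* tuned per dataset.

Two caveats discovered while validating the recovery path are worth
recording. First, "raising the center threshold can only reduce the
instance count" holds for circular cells (their distance maps decrease
radially, so superlevel sets shrink while staying connected) but can
fail on a lattice for elongated cells: the discrete ridge of a long
ellipse can carry its exact maximum at two pixels with a slightly lower
saddle between them, so a very high threshold splits the seed in two.
Second, the same mechanism is what makes carved, non-convex cells (cells
trimmed around earlier neighbors when clumps form) occasionally split —
a mild relative of the peanut ambiguity. At the default 0.5 threshold
neither effect is material: the seeded 20-image round-trip suite scores
mean DET ≈ 0.99 and mean SEG ≈ 0.95.

### Full-frame inference

Frames are processed as 256×256 patches with a 32-pixel margin on each
side, the stride therefore 192 pixels, and the last tile per axis
clamped so it ends at the frame edge. At stitch time each pixel is owned
by exactly one tile — the one whose *central region* (patch minus
margin, extended to the frame edges for border tiles; earlier tiles win
where the clamped final tile overlaps) contains it. This discards
predictions made near a patch border, where the network sees objects
partially out of frame, and makes `stitch(make_tiles(x))` an exact
identity — which in turn makes the oracle-predictor inference path
bit-exact end to end, a property the tests assert on mixed frame sizes.
Frames smaller than one patch are reflection-padded (no artificial hard
edges) and cropped back.

Preprocessing is CLAHE first (on the integer intensity scale; clip
limit 2, 8×8 tile grid — the de-facto standard defaults, configurable),
then standardization to zero mean and unit variance. The *population*
standard deviation is used, making the two-value closed form
`{0, 2} → {−1, +1}` exact; constant frames are mapped to all zeros via a
1e-8 floor on the standard deviation rather than raising an error, so a
blank well never aborts a batch.

## Training

The trainable patch predictor is a small fully-convolutional network
(5×5 → 3×3 → 1×1 convolutions, 8 hidden channels, ReLU between, sigmoid
output; ~800 weights). The sigmoid guarantees the [0, 1] output contract
of every predictor. The size is a deliberate choice: the training-loop
properties worth testing at the desk — loss decrease, bit-reproducible
histories, the optimizer schedule being followed step for step — depend
on the loop, not on model capacity, and this net trains in about half a
minute on one CPU core.

Optimization is AdamW (decoupled weight decay applied to convolution
weights, not biases) under L2 loss, with the reference hyperparameters
as `train_config()` defaults: learning rate 1e-4, weight decay 0.1,
$\beta_1 = 0.9$, $\beta_2 = 0.999$, batch size 2, 40 epochs, linear
warm-up over 250 steps followed by linear decay to zero. Desk-scale
smoke runs (8 images × 5 epochs = 20 steps) cannot accommodate a
250-step warm-up — the schedule requires warm-up < total steps — so such
runs pass an explicit shorter warm-up and a larger rate (0.05): 1e-4 is
a *fine-tuning* rate for a large pretrained encoder, while a sub-1k
parameter network trained from scratch sits in a different regime.

Each epoch draws one augmented 256×256 patch per training image:
horizontal mirroring (p = 0.5), rotation uniform on [−180°, 180°],
isotropic rescale on [0.8, 1.2], brightness on [0.95, 1.05], and
inversion (p = 0.5). Distance maps receive only the three geometric
operations — brightness has no meaning for a geometric target, and
inversion would destroy it. Geometric warps use bilinear interpolation
about the frame center with reflection padding for images and zero
padding (the semantic background) for maps, whose values are re-clamped
to [0, 1] after interpolation. On standardized images inversion is
negation, equivalent to full-scale intensity inversion up to the removed
affine statistics. Augmentation draws are keyed by
`(seed, epoch, image index)`, so any patch of any run can be regenerated
in isolation.

## Evaluation measures

SEG is the mean, over *reference* cells, of the Jaccard index against
the majority-matched prediction — a prediction matches a reference iff
it covers strictly more than half of it (which makes the match unique) —
with unmatched references contributing 0. DET is $1 - \min(\text{AOGM-D},
\text{AOGM-D}_0)/\text{AOGM-D}_0$, where AOGM-D counts weighted
node edits turning the predicted detection graph into the reference one:
10 per missed reference, 1 per spurious prediction, 5 per extra
reference covered by one prediction (a needed split); AOGM-D$_0$ is the
cost of building the reference from nothing. The weights are the
standard values for these measures and are exposed as parameters. Both
implementations are verified in the tests against an independent
brute-force oracle that enumerates the full overlap table on small
random masks, and against hand-computed worked examples (J = 3/6 = 0.5
for the three-of-four-pixel case; DET = 1 − 1/20 = 0.95 for two true
detections plus one spurious).

## Culture statistics

Per image: cell count; mean cell area (pixels, averaged over cells;
reported 0 for an empty frame); confluency, the fraction of frame pixels
covered by cells; and per-cell neighbor counts. Two cells are neighbors
when their supports come within `2 * neighbor_radius` pixels of each
other (Euclidean; default radius 3 px, i.e. a 6 px reach), computed with
exact distance transforms. The symmetric two-sided definition was chosen
over "dilate one cell and test overlap with the other" so that the
relation is exactly reproducible by a brute-force minimum-pixel-distance
check, which the tests run.

## The synthetic generator

`generate_culture()` emulates the properties of label-free cultures that
matter to this pipeline: convex-to-moderately-elongated cells (ellipse
bases, axis ratio 1–2.5, semi-axis 6–12 px), a configurable clumped
fraction placed touching an existing cell (touching but never merged —
the hard case for instance separation), soft blurred edges (σ = 1.5 px),
a linear field-brightness gradient (amplitude 30 on the 8-bit scale),
additive Gaussian noise (σ = 6), and both bright-on-dark and
dark-on-bright polarity. Separated cells keep a one-pixel background
moat; every cell is 4-connected with a nonempty 1-px-eroded interior, so
distance-map round trips are well posed. Placement retries are bounded:
very dense requests return fewer cells (the actual count is reported)
rather than looping, which in practice saturates observed confluency
around 0.45–0.5. `generate_suite()` jitters confluency (0.1–0.6 target
band), contrast (±30%), and polarity across images, all derived from one
seed.

What the generator does **not** emulate: phase-contrast halos,
out-of-focus debris, fluorescence multi-channel structure, peanut-shaped
dividing cells, and real annotation noise. Passing round-trip tests on
these images therefore demonstrates that the encoding → thresholding →
watershed machinery is correct and that the tiling/stitching path is
lossless; it does not certify segmentation accuracy on real micrographs,
which depends on a trained predictor at realistic scale.

## Numerical choices and problem sizes

* Exact Euclidean distance transforms throughout (verified against an
  $O(P^2)$ brute-force search at tolerance 1e-6; agreement is in fact
  exact). Per-cell transforms run on the cell's bounding box with a
  one-pixel zero ring, which implements the "frame border is boundary"
  convention.
* Watershed flood order: strictly by map height, FIFO within ties, so
  results are deterministic; 8-connectivity for seeds and flooding.
* Encoding is equivariant under mirroring and 90° rotations bit-exactly,
  and the tests assert it.
* Test and acceptance problem sizes: masks up to 32×32 against the
  brute-force encoder oracle (50 cases), 100 random ≤16×16 mask pairs
  against the metrics oracle, 20-image 256² round-trip suites, mixed
  256²/300²/512² frames for the lossless-path check, and 8-image ×
  5-epoch training smoke runs — sizes at which every property is checked
  in a few minutes on one core while still exercising multi-tile
  stitching, clumped geometry, and both polarities.
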