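---
title: "Methods: automated scoring of C. elegans swimming postures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated scoring of C. elegans swimming postures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The assay and the problem

Aging *C. elegans* with compromised neuronal branched-chain amino acid
metabolism develop a spasm-like "curling" phenotype while swimming: the
head or tail contacts a noncontiguous body segment, up to a fully closed,
self-occluding loop. The fraction of animals caught in curled postures in
a snapshot of a well is a quantitative proxy for this motor defect, and a
drug that lowers that fraction relative to vehicle is a candidate hit.
wormsnap implements the full segment–train–quantify workflow for such
snapshot assays: object detection in single-well images, a five-class
convolutional network over standardized mask crops (Coiled, Curled,
Near-curled, Non-curled, Censored), ensemble scoring of snapshots, and
the downstream screen statistics — plus a synthetic-image generator built
on the same body model, so every stage can be trained and tested without
any real image data.

# The body model

A worm body is a planar tube around a centerline. With `u` the
normalized arclength in `[0, 1]`, the tangent angle and the half-width
profile are cubic B-spline curves with eight coefficients each:

$$\Theta(u) = \sum_{j=1}^{8} \alpha_j \, \phi_j^3(u), \qquad
  R(u) = \sum_{j=1}^{8} r_j \, \phi_j^3(u),$$

and the body surface follows by integrating the unit tangent along the
centerline and offsetting by `R(u)` along the normal:

$$X(u) = X(0) + L \int_0^u \begin{pmatrix}\cos\Theta(s)\\ \sin\Theta(s)
  \end{pmatrix} ds + R(u)\begin{pmatrix}-\sin\Theta(u)\\ \cos\Theta(u)
  \end{pmatrix}.$$

Design choices the model statement leaves open, and how this package
resolves them:

* **Knot vector.** Clamped uniform cubic knots on `[0, 1]`
  (`0,0,0,0, 0.2, 0.4, 0.6, 0.8, 1,1,1,1`). This gives nonnegative basis
  functions, a partition of unity (so a constant coefficient vector is a
  constant function), and endpoint interpolation (`R(0) = r_1`,
  `R(1) = r_8`), which makes tapered head/tail tips easy to state.
* **Integration.** The centerline integral uses the composite trapezoid
  rule on the sampling grid; the error is `O(h^2)` in the grid step, and
  the closure test for a full-turn geometry budgets exactly that.
* **Coordinates.** Geometry lives in standard Cartesian coordinates
  (y up); rasters are `width x height` matrices with y down, and the
  y-flip happens in exactly one place at the raster boundary.
* **Head/tail orientation** of a fitted centerline is arbitrary; it is
  fixed lexicographically by endpoint coordinates. All curling metrics
  are orientation-invariant, so this is only a determinism device.

## Rendering and fitting

`render_mask()` rasterizes the tube as a union of disks along a dense
centerline sampling (spacing 0.25 px), which handles self-occluding
coils naturally: the union stays a single 8-connected component and a
closed loop encloses a background hole. The hole is the operational
signature of the Coiled class, following the classic binary-image rule
for coiler detection.

`fit_geometry()` inverts the renderer: Zhang–Suen thinning, longest path
through the skeleton graph (double breadth-first search), spur pruning
(branches under 10% of the main path are thinning artifacts on wide
bodies; anything longer signals an unfittable mask), tip recovery by
walking each end's tangent until the mask is left (thinning erodes
tapered tips), sub-pixel transverse refinement of each centerline point
to the parabolic peak of the distance transform (the skeleton is
quantized to pixel centers; without this step a half-pixel offset costs
a full row of rendered coverage), and linear least squares of both
profiles onto the spline basis. Half-widths come from the distance
transform along the refined centerline minus a 0.1 px calibration offset
measured against rendered tubes of known radius. Masks with holes or
persistent branches raise a typed `wormsnap_unfittable` condition so
callers censor rather than crash.

# The synthetic generator

The generator is the package's study population, not a test fixture; its
defaults are the assay conditions used throughout the tests.

* **Geometry.** Body length 50–70 px at the default image scale, maximum
  half-width 2.2–3.0 px, tapered width profile with end coefficients at
  12% of the maximum. Orientation uniform; curvature direction random.
* **Posture classes.** The source assay defines classes by example
  images only; wormsnap uses operational boundaries on total turning
  $T = \int_0^1 |d\Theta/du| \, du$: Non-curled `T < pi` (undulation
  amplitude drawn so `T` lands in `0.25–0.85 pi`), Near-curled
  `pi <= T < 5pi/3` (arcs at `1.06–1.58 pi` plus a small wiggle), Curled
  `T >= 5pi/3` with head–tail distance under 1.5 mean body widths (arcs
  at `1.86–1.96 pi`), Coiled a closed self-occluding loop whose rendered
  mask has a hole (arcs at `2.1–2.6 pi`). Candidates are resampled until
  they pass their own rule as re-measured by the geometry module, so
  labels are correct by construction. The gaps between class ranges are
  deliberate: transitional postures between adjacent categories are the
  dominant error source in the real assay, and the generator's margins
  keep ground truth unambiguous.
* **Censored pool.** 40% entangled worm pairs, 20% progeny-scale debris
  specks, 20% body fragments, 20% ragged high-noise bodies — mirroring
  the reasons real detections are censored (entangled worms, debris,
  progeny, uninterpretable masks). Every crop is forced to exactly one
  8-connected object, and a "pair" must genuinely touch: an untangled
  pair reduced to its largest component would be an ordinary single worm
  carrying a Censored label, i.e. pure label noise.
* **Crop assembly.** Training crops are produced by the same
  standardization path the segmenter uses on well images: the shaded body
  is composited onto the well background (0.07 plus sensor noise), and
  the grayscale is retained under the object's mask dilated by `4A/P`.
  Crops therefore carry the same background ring inside the dilated mask
  that the deployed classifier sees; training on zero-background crops
  instead creates a train/deploy domain shift that measurably degrades
  end-to-end counts.
* **Well snapshots.** 384 px frames, well radius 170 px, dark background
  (0.03 outside / 0.07 inside the well), a Gaussian-profile meniscus
  ring just inside the rim, additive Gaussian sensor noise (sd 0.02),
  worms shaded by a cylindrical elevation profile (bright spine) at
  intensity 0.55–1.0. The spine-bright shading matters: it gives the
  body interior nonzero gradient and texture, as real worms have, so
  both the gradient and the texture detection paths see solid bodies.
  Debris is half sub-worm specks (caught by the area filter) and half
  jagged star-shaped blobs (caught by the jaggedness filter). Worm
  placement uses a hard-core minimum spacing with a controllable
  overlapping fraction; overlapped pairs are ground-truth flagged since
  the right automated answer for them is Censored.
* **Screens.** Per-well worm counts are Poisson with the template's
  `n_worms` as mean (the real assay averaged about 12 worms per well).
  Postures are redrawn independently for every snapshot: stills are
  taken 30 s – 2 min apart, long enough for swimming postures to
  decorrelate, and treating them as independent draws is what makes the
  binomial pooling analysis valid. A condition's `decay` field drifts
  its curl probability linearly in time, emulating the episodic-swimming
  decay of the curling signal after transfer to liquid buffer.

What the generator does **not** emulate: hydrodynamics and realistic
swimming dynamics, out-of-focus blur, illumination drift between wells,
bubbles, bacterial clumps, or the full morphological variety of real
debris. Passing tests therefore demonstrate the correctness of the
pipeline's logic and its statistical behavior under the stated
conditions, not field performance on any particular microscope.

# Detection

The gradient path (`detect_objects()`): Sobel gradient magnitude, a
256-bin histogram over the well interior, multilevel Otsu thresholds
(exhaustive between-class-variance maximization; ties toward the lower
threshold), binarization at the configured level, morphological closing
with a 3x3 kernel, selective hole filling (enclosed background
components of at most 4 px are sealed; anything larger is preserved so a
coil's hole survives binarization), 8-connected labeling, and three
filters: area within `0.1–8x` a reference worm area (220 px^2 at the
default scale), exclusion of components within 2 px of the well circle
(meniscus artifacts), and contour jaggedness.

Jaggedness is the ratio of the raw contour perimeter to the perimeter
after resampling to `n_node = 60` equally spaced nodes and one pass of a
circular 3-point moving average; smooth tubes score near 1, star-shaped
debris scores far above the default 1.3 cutoff. The smoothing recipe is
this package's choice; only the ratio itself and the cutoff are given by
the source method.

Crop standardization dilates the object mask with a disk of radius
`4A/P`, keeps grayscale pixels under the dilated mask, deletes pixels of
neighboring labeled objects (keeping the component that overlaps the
target), and pads — or isotropically rescales, for objects larger than
the 128 px input — into the network frame.

# The network and training

The architecture is fixed: conv 16@3x3 (stride 1, pad 2), 3x3 max-pool
(stride 1, pad 1), conv 32@3x3 (pad 1), 2x2 max-pool (stride 2), conv
64@3x3 (pad 1), then fully connected 100–100–5 with dropout 0.25 before
the output layer and a softmax. The source description contains two
mutually exclusive sentences for the third convolution (16 filters pad 2
vs. 64 filters pad 1); this package adopts 64/pad 1 — monotone filter
growth is standard practice — and exposes the alternative through
`network_architecture()`. Pooling-layer padding and activations are
unstated; pad 1 (size-preserving) and ReLU are used. Dropout placement
is unstated; it sits before the final fully connected layer.

Optimization follows the stated settings exactly: mini-batch 256, SGD
momentum 0.9, L2 penalty 1e-4, learning rate 0.005, a stratified
75/10/15 train/validation/test split, and per-epoch shuffling with fresh
random rotation (uniform 0–360 degrees, bilinear) and independent x/y
reflections of every training image. Weights at the best validation
accuracy are returned; training stops at the epoch cap (default 30), on
a validation plateau (patience 5), or once validation accuracy reaches
`val_stop`. The implementation is single-precision im2col + GEMM on the
BLAS that R links, with analytic gradients verified against finite
differences. Initialization is He-normal with a configurable gain, and
the input byte scale is configurable (`input_scale`); both default to
the plain choice (gain 1, inputs in `[0, 1]`).

A divergence guard converts a NaN loss into an error advising a lower
learning rate rather than returning garbage weights.

# Snapshot scoring

The classifier path (`analyze_snapshot()`) intentionally does not reuse
the detector's single threshold: the snapshot is passed through a 5x5
local standard-deviation filter (a thin worm always spans an intensity
edge within the window, so the whole body responds), binarized at all
three thresholds of a 3-level Otsu decomposition, and 8-connected
components from the three nested binaries are matched across
binarizations by IoU >= 0.5. Each matched object contributes up to three
member components, each dilated at four disk radii
(`{0.5, 1, 1.5, 2} x 4A/P` — the count of sizes is given by the source
method, the radii are this package's choice), for up to 12 standardized
crops. The network scores all of them and the object's class is the
argmax of the averaged probability vector; ties break toward Censored,
matching the strict-censoring philosophy of the assay. Averaging over
masks from three thresholds removes the bias any single binarization
would impose.

Censored objects are retained in the result table but excluded from all
posture statistics. Manual overrides set an audit flag (also for no-op
overrides) and append to a provenance log.

# Assay statistics

Snapshots and rounds pool into one count vector per well; the well is
the statistical unit, matching how replicate counts are reported in this
assay type (n wells totaling m worms). Wells with fewer than 3
classified worms are excluded. Three metrics are available — percent
Coiled (the default headline metric, the posture with the largest
treatment-to-control mean ratio), percent Coiled+Curled, and percent
Coiled+Curled+Near-curled (the comparator for manual stopwatch scoring,
which cannot distinguish the curled subtypes). Screens are
vehicle-normalized (vehicle = 100% by construction) with hits below
50%. Two-group comparisons use the two-tailed pooled-variance t-test;
multi-group comparisons use one-way ANOVA with Dunnett contrasts against
the designated control, with multivariate-t quantiles computed by
multcomp (numerically, not from printed tables). The time decay of the
treatment-to-control ratio after transfer to liquid is summarized by an
ordinary least-squares line of per-round mean ratios on round start
times.

Open pooling question: when a well is imaged over multiple rounds the
source does not state whether rounds are averaged or pooled; wormsnap
pools counts (and keeps round identifiers in the object table so the
other convention remains computable).

# Problem sizes and budgets

All shipped tests and the acceptance script run single-core. The
convolutional network is the expensive component: one optimizer update
(mini-batch 256) costs about 11 s on one core, independent of dataset
size, so wall time is set by updates, not epochs. The package's own
validation therefore runs at reduced, documented scales:

* geometry round trip: 50 random geometries plus 10 C-shaped arcs;
* detection: 40 synthetic wells, about 400 worms;
* network training: one 5x150-crop dataset (vs. the source database of
  32,000), epoch cap 10 (about 30 optimizer updates), one training run
  shared by the training-accuracy and end-to-end blocks;
* end-to-end ratio recovery: 2 conditions x 7 wells x 4 stills of 12
  worms through the full image pipeline;
* screen logic: 50 replicates of a 51-condition screen at the truth
  level (hit calling consumes counts, not pixels), 10 wells per
  condition;
* the acceptance script repeats the same computations at slightly
  smaller sizes to fit its own budget.

Accuracy at these scales is compute-limited, not model-limited: on a
longer diagnostic run (250 crops/class, 60 epochs, about 240 updates)
test accuracy reaches 0.87 and is still rising, with residual errors
concentrated at the Coiled/Curled boundary and among entangled pairs. A
full-scale run (800 crops per class, 30 epochs, about 360 updates) is a
multi-hour single-core computation; the training pipeline is identical,
only the problem size differs.

# Known limitations

* No tracking across frames: stills are scored independently, so speed
  and thrashing frequency are out of reach by design.
* Entangled worms are censored, never untangled; crowded wells lose a
  larger fraction of animals to censoring, which reproduces the real
  assay's behavior but means per-well counts are biased low at high
  densities.
* The posture-class boundaries are operational stand-ins for a
  human-labeled consensus; the thresholds are configurable but the
  defaults should not be read as a biological definition.
* The fitted body model assumes a non-self-occluding mask; Coiled
  objects are classified by topology, not fitted.
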