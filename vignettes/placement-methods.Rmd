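---
title: "Automated scan and pre-scan volume placement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated scan and pre-scan volume placement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bilateral breast MRI requires two kinds of graphically prescribed volumes
before diagnostic imaging can start: the **scan volume** (the imaging field
itself, square in the axial plane, with a separate superior-inferior
coverage) and a pair of **pre-scan volumes** (local calibration regions, one
per breast, over which shims, center frequency and gains are optimized).
Technologists place these boxes by hand on a fast 3-plane scout acquisition;
manual placement is slow and variable between operators. `scoutbox`
implements an automated placement pipeline: binarized maximum-intensity
projections of the three scout orientations feed a convolutional regressor
that directly emits the placement parameters, with Monte-Carlo-dropout
uncertainty attached to every prediction.

All geometry lives in a fixed patient frame: LR = +x (patient left
positive), AP = +y (posterior positive), SI = +z (superior positive), in
centimetres. Boxes are strictly axis-aligned; the clinical parameterization
contains no rotation.

## Volume parameterizations

The scan volume is described by five values: LR/AP/SI position, the axial
field of view (shared by the LR and AP edges), and the SI coverage. The
bilateral pre-scan pair is described by nine values: two independent centers
plus one shared size, reflecting the scanner convention that both
calibration volumes use a common geometry. `scan_params_to_box()` and
`prescan_params_to_boxes()` convert both to plain boxes, the currency of
every metric in the package.

## Geometric metrics and losses

Agreement between a predicted and a reference box is measured by:

* **3D IoU** — intersection over union of volumes;
* **2D IoU** — rectangle IoU of the axial/sagittal/coronal projections;
* **center distance** (cm), **signed percent volume error**, and the
  **percent of the reference volume covered** by the prediction;
* **parameter RMSE** (cm) over the 5- or 9-vector;
* **cIoU** — the sum of the scan, left and right pre-scan 3D IoUs per exam,
  ranging 0 to 3.

The 3D **generalized IoU** extends the familiar 2D definition verbatim to
volumes: `GIoU = IoU - (|C| - |union|) / |C|`, with `C` the smallest
axis-aligned box enclosing both operands. It equals the IoU when the
enclosure is tight and tends to -1 as disjoint boxes separate, which makes
`1 - GIoU` usable as a training loss even when a prediction does not overlap
the target at all. Two properties worth remembering: `GIoU <= IoU` always,
and a useful intuition pair — a 10 cm cube overestimated by 1 cm on every
side still has IoU 0.75, while the same cube displaced 1 cm along each axis
(1.7 cm of total displacement) drops to IoU 0.57. Position errors hurt more
than size errors.

Degenerate predicted sizes (an untrained network can emit negatives) are
clamped to 0.1 cm with a warning before metric computation; evaluation must
be total.

## The synthetic phantom

No clinical scouts ship with the package, so the `phantom` module generates
prone bilateral-breast anatomy with known ground truth: two breast
ellipsoids anterior to a chest-wall plane, a thorax block containing dark
lung fields and a bright heart surrogate, optional arm blocks, and air
background. Intensities are piecewise constant (breast tissue 1.0, air 0)
with additive Gaussian noise; there is deliberately no MR physics — the
downstream masks only need geometrically plausible silhouettes.

Ground truth encodes the clinical placement guidelines deterministically:

1. each breast's bounding box is expanded by exactly 1 cm per face ("around
   a 1 cm margin" needs one number to be reproducible);
2. boxes are clipped at the patient midline so the pair never overlaps;
3. both boxes take the element-wise maximum of the two sizes (the shared
   size constraint) and centers are pushed back off the midline if needed —
   the smallest common size covering both breasts with the margin;
4. the scan volume is the smallest square-axial box covering both expanded
   breast boxes, with 2 cm of extra superior coverage toward the axilla.

`check_guidelines()` audits any candidate pair against the four goals
(containment, face margins within 1.5 cm, under 20% thorax inclusion, zero
mutual overlap) on voxelized tissue masks. Random anatomies
(`random_phantom_spec()`) draw semi-axes and positions so ground-truth sizes
bracket typical clinical volumes (pre-scan near 13 x 11 x 16 cm; scan
roughly 22-32 cm axial FOV with 15-21 cm SI coverage — slightly smaller than
a clinical average scan because the phantom has no axillary bulk). Left and
right breasts differ by a small asymmetry, bounded at 0.075 cm per
semi-axis, so that the shared-size reconciliation in step 3 never pushes a
face margin past the checker tolerance; and both breasts stay clear of the
midline, as in prone positioning with medial separation. The
`arms = "overhead"` mode stretches the ellipsoids in SI and narrows them
axially, emulating the elongated pendant shape that is a known hard case for
placement. Generation is bit-reproducible from the spec's seed.

What the phantom does **not** emulate: MR contrast and coil shading,
fibroglandular texture, implants, post-surgical anatomy, or scanner-to-
scanner protocol differences. A model that recovers phantom ground truth
demonstrates that the pipeline (preprocessing, architecture, losses,
cross-validation, uncertainty) is sound — it says nothing about clinical
performance, which depends on data the package cannot ship.

## Preprocessing

Each orientation of the scout is reduced to a maximum intensity projection
and binarized with Otsu's method (256-bin histogram over the image range,
threshold maximizing between-class variance, ties resolved toward the
lowest threshold — a fully deterministic variant). Binary masks are
resampled to a common square resolution with nearest-neighbour
interpolation (which preserves binarity) after zero-padding to preserve
aspect; each mask keeps an affine so pixels map back to patient
centimetres. No morphological cleanup is applied by default; an optional
largest-component flag exists. The three masks are stacked as the three
channels of one input image — the simplest faithful reading of "three
binary masks as input".

## Network, training, uncertainty

The regressor is AlexNet-shaped: five convolutional layers (kernels
11/5/3/3/3, strides 4/1/1/1/1, max-pooling 3x3/2 after layers 1, 2 and 5)
and three fully connected layers, with dropout (rate 0.5) between the fully
connected layers only. Channel and hidden widths are the AlexNet widths
scaled by a configurable multiplier, 0.25 by default, so the whole pipeline
trains on one CPU; the head emits 5 or 9 values. Targets are normalized by
a fixed reference length of 45 cm (the upper range of clinical scout fields
of view) so regression targets sit in roughly `[-1, 1]`; every metric is
computed after conversion back to centimetres.

Training uses RMSprop with batch size 32 and five-fold cross-validation.
Each source case is replaced by five shifted copies (whole-pixel shifts up
to ±3 cm per axis; position targets shift with the anatomy, sizes do not),
and augmented copies always inherit their source case's fold — a leakage
guard asserted on every run. Both losses are available for both heads:

* **RMSE** over the normalized parameter batch;
* **GIoU**: mean of `1 - GIoU3D` over boxes and batch, with predicted sizes
  passed through a softplus so raw regression outputs always form valid
  boxes.

Defaults follow the combination that maximizes held-out 3D IoU: RMSE for
the scan head, GIoU for the pre-scan head. The learning-rate default is
per-loss: 1e-4 for RMSE but 1e-3 for GIoU. The GIoU surface is nearly flat
when predicted boxes are small and disjoint from their targets (exactly the
random-initialization regime), and RMSprop's per-step movement is bounded
by the learning rate, so at 1e-4 the size parameters cannot travel the
~13 cm they need within a 30-epoch budget; at 1e-3 the loss reliably
escapes the plateau. This matches the wider experience that GIoU regression
is harder to optimize than parameter-space losses.

At inference, dropout stays active: `mc_dropout_predict()` averages `T`
stochastic passes (100 by default) into the placement prediction and
reports the per-parameter sample standard deviation, in centimetres, as the
uncertainty. With `T = 1` the standard deviation is reported as 0 and
flagged undefined; with dropout rate 0 the uncertainty is exactly 0.
Averaging is done in centimetre space (the normalization is linear, so this
is equivalent to averaging normalized outputs). Uncertainties are reported
per parameter, never aggregated, mirroring how uncertainty tables are read
clinically. The package does not calibrate uncertainties against empirical
error.

## Evaluation conventions

Cohort summaries report the 5th percentile, median and 95th percentile of
every metric, using linear interpolation between order statistics
(`stats::quantile` type 7) — the rule is stated because percentile
definitions differ and reproducibility requires fixing one. Bilateral
predictions are assigned to sides by the sign of the predicted center's LR
coordinate (left = +LR), with ties broken by nearest truth center; each
side is scored independently against its own truth box. The overlap metric
always uses the human-placed (reference) volume as denominator. Group-wise
summaries (the analogue of per-scanner reporting) produce box-plot-ready
statistics with outliers beyond 1.5 IQR. Statistical tests between sides
are deliberately not part of the report.

## Numerical choices and problem sizes

* Box metrics are closed-form interval algebra; the test suite checks them
  against an independent voxelization oracle (boxes rasterized on a 0.05 cm
  grid) to within 0.01 on a thousand random pairs, and all loss gradients
  against finite differences.
* The GIoU gradient takes subgradients at the (measure-zero) min/max kinks.
* Synthetic experiments in the test suite run at a 32-pixel mask resolution
  with 96-pixel scout rasters and a 300-phantom cohort, five-fold
  cross-validated for 30 epochs per fold — sizes chosen so the full
  recovery experiment, including Monte-Carlo evaluation, completes in
  minutes on a single CPU while still training from thousands of augmented
  samples. The 224-pixel default resolution is the AlexNet-native choice
  for real scouts.
* One global seed fans out to per-stage seeds through a fixed integer
  derivation, so pipeline stages are independently reproducible and two
  runs with the same configuration are bit-identical.

## Known limitations

* The clinical reference performance (median 3D IoU near 0.7 on real
  exams) is not reproducible here: it depends on unreleased patient data.
  Phantom-recovery results exercise the machinery, not clinical accuracy.
* Scout input is supported as NIfTI plus a JSON sidecar (and everything the
  phantom writes); DICOM series reading is not implemented because no DICOM
  reader is available in the package's dependency footprint.
* The exact convolution kernel sizes and strides of the original clinical
  model are not specified anywhere the package can cite; the AlexNet defaults are used.
* Whether the three masks should enter as channels or as separate branches
  is likewise an open choice; channels are used.
* Oriented (rotated) boxes, implant/mastectomy anatomy, and artifact
  grading of scouts are out of scope.
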