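---
title: "Identifying flagella by their width: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying flagella by their width: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flagtrace)
```

## The problem and the idea

Tracking a beating flagellum in videomicroscopy of a free-swimming cell
requires separating the flagellum from the cell body in every frame. Simple
intensity thresholding cannot do this: in phase-contrast imaging the
flagellum and body usually share the same grey values. What does
distinguish the flagellum is geometry. The axoneme — the conserved 9+2
microtubule core — runs the whole length of the organelle and fixes its
diameter, so at optical resolution the flagellum appears as a filament of
*approximately constant width*, in contrast to the broader and more varied
cell body. Accessory structures such as the trypanosomatid paraflagellar
rod thicken the filament but leave its visible width near-constant.

`flagtrace` turns that trait into a fully automatic segmentation:

1. **Binarise** the frame into a single-cell mask (`binarize()`), after
   optional background subtraction (`subtract_background()`).
2. **Medial axis transform** (`medial_axis_transform()`): the pixel-wise
   product of an exact Euclidean distance map and a
   connectivity-preserving skeleton. On the medial line the transform
   value is the local *half-width* of the cell in pixels.
3. **Identify** the flagellum in the width data — by default as the
   largest connected skeleton region whose width is close to the modal
   width (`modal_segment()`), since a long flagellum dominates the width
   histogram's mode; alternatively by derivative analysis of the width
   profile (`derivative_segment()`).
4. **Trace** the identified pixels into an ordered centerline
   (`trace_flagellum()`), locate the attachment point, and optionally
   summarise a frame sequence into beat parameters (`beat_parameters()`).

Every step is automatic; no per-frame input is ever requested.

## The transform

The distance map is the exact Euclidean distance to the nearest background
pixel (computed via `EBImage::distmap`, which the test suite verifies
against a brute-force oracle, pixel for pixel). The skeleton is computed by
sequential deletion of *simple points* — border pixels whose removal
provably preserves local topology — in axis-interleaved directional
sub-passes (N, E, S, W), with endpoints preserved. Deleting only simple
points guarantees that the skeleton of a connected region is connected and
that holes survive: a disk thins to one or two central pixels, an annulus
to a closed loop. Foreground uses 8-connectivity and background
4-connectivity, the standard topologically consistent pairing. Each
directional sub-pass operates on a snapshot of that direction's border
pixels so exactly one layer peels per pass; this keeps the skeleton
centered (within the ±1 px that rasterisation permits).

Two consequences are worth knowing. First, this thinning is deliberately
spur-free: a convex bulge (e.g. a disk) collapses to a point rather than
sprouting ridge branches, which matches the method's needs but means the
skeleton's width disks do not cover sharp convex corners of arbitrary
shapes. Second, directional tie-breaking makes the skeleton equivariant
under translation but only approximately equivariant under rotation; width
statistics agree across 90° rotations to well under a tenth of a pixel.

## Identifying the flagellar region

The width histogram uses bins of 1 px (`bin_width_px`), matching the
near-discrete values (1, √2, 2, √5, …) the transform takes on rasterised
images. Because those values scatter within a bin, the bin *center*
systematically misestimates the flagellar half-width; the **modal width is
therefore refined as the mean of the widths inside the modal bin**. Ties
between bins break toward the smaller width — the flagellum, not the body,
is the thin structure of interest.

Skeleton pixels within `modal_tolerance_px` (default 1 px, absorbing the
√2 rasterisation jitter) of the refined mode form the candidate regions;
the largest 8-connected candidate is the flagellum. Candidates smaller
than `min_region_px` (default 5 px) are speckle. Before selection the
candidates are passed through `stitch_segments()`: while two distinct
regions have endpoints closer than the stitch radius — by default twice
the modal half-width, i.e. the approximate visible flagellum width — they
are joined by a straight rasterised bridge. This restores connectivity
when a flagellar crossing locally inflates the transform and splits the
thresholded region, while the radius bound prevents joining separate
well-segmented structures; on a clean segmentation stitching is a no-op.

The **attachment point** is found from the selected region's path: of its
two ends, the body side is the one whose continuation along the full
skeleton has the larger mean width over the next 5 pixels. That end is
then refined to the point where the flagellar width plateau actually ends:
trailing points are trimmed while their width exceeds the plateau ceiling
(the maximum width over the path interior plus half a bin), or, where the
tolerance window cut the region short because body adjacency inflated the
transform, the estimate is extended along the full skeleton while widths
stay under the same ceiling. On the synthetic suite this places the
attachment within 3 px of ground truth in every frame.

Tracing follows the **longest tangent-consistent path** through the
region: walks start from every region endpoint and the longest wins, so a
residual body stub at flagellar width cannot capture the trace. At a
junction the walk continues along the branch whose initial direction
(averaged over `tangent_window` = 5 px) best matches the incoming tangent;
two filaments crossing at ~90° are each traced straight through. This
window balances rasterisation noise against curvature; junction handling
is appropriate for all but near-tangential crossings, which remain a
documented limitation.

The alternative **derivative analysis** walks the width profile from the
flagellar tip and computes a `derivative_step`-sample forward difference
of width with respect to arclength; the first value exceeding the running
median plus `outlier_k` (default 3) times the running MAD — floored at
0.1 px/px so an exactly constant history cannot make every wiggle an
outlier — marks the attachment. The method works, but it is markedly more
sensitive than modal analysis to the step choice (on the synthetic suite,
2-step differences succeed in roughly half the frames where 3-step
succeeds in most), which is why `modal` is the default method.

## The phantom generator: what it emulates and what it does not

`make_phantom()` draws an elliptical body (semi-axes 11 × 7 px by default,
optionally tapered) joined to a tube of constant half-width around the
parametric curve `y(s, t) = A sin(2πs/λ − 2πf t)`, rasterised by the rule
*a pixel is foreground iff its center lies in the analytic region*, with
exact per-frame centerline, attachment and mask ground truth. The default
conditions — visible flagellar width 3 px, flagellum 66 px, amplitude
4.3 px, wavelength 28 px, 29 Hz beat sampled at 200 Hz for 100 frames —
correspond to a promastigote-like cell at roughly 0.3 µm/px: amplitude
1.29 µm, wavelength 8.41 µm, a 20 µm flagellum, in frames comparable to
136 × 76 px video. Degradations reproduce standard image-quality losses:
sensor-binning downsampling (block averaging), additive Gaussian noise of
sd 10 on the 0–255 scale with 8-bit clipping, Gaussian blur of radius
2 px, and pixel-wise multiplication by a horizontal black-to-white ramp
emulating non-uniform illumination.

The phantom is deliberately idealised. It has binary intensities with no
phase-contrast halo or shade-off; its wave is a pure travelling sine with
the same amplitude at the base as at the tip, whereas real flagella are
anchored and often show amplitude envelopes; the body is a smooth ellipse
rather than an irregular blob; and the scene contains a single cell.
Passing the synthetic suite therefore demonstrates the geometric and
algorithmic correctness of the method — exact transform values, connected
skeletons, correct region selection, tolerant tracing — but not robustness
to optical artefacts beyond the four modelled degradations. One notable
consequence of the equal-amplitude wave is that the attachment point
itself oscillates by ±A, which makes the junction geometry *harder* than
an anchored flagellum would be.

## Beat parameters

Trace sequences are aligned to a body frame (origin at the mean attachment
point, or the per-frame body centroid when masks are supplied; x-axis
along the principal axis of the pooled trace points, oriented toward the
tips). The estimators are chosen to be exactly invertible on the
generator's own wave model:

* **Dominant frequency**: peak of the Hann-windowed periodogram of the
  transverse displacement sampled where traces cross the midpoint of the
  common x-range (a fixed-x signal is exactly sinusoidal under the wave
  model; an arclength midpoint would not be). Resolution is one spectral
  bin, `frame_rate / n_frames`.
* **Amplitude**: √2 × RMS of that signal — exact for a pure sinusoid.
* **Wavelength**: 2π/k from per-frame least squares of
  `a sin(kx) + b cos(kx)`, profiled over k (grid search then local
  refinement). Fitting per frame avoids any dependence on the estimated
  frequency.
* **Length**: mean trace arclength, × `pixel_size_um`.

Results carry a low-confidence flag when fewer than two beat periods are
covered, frames were excluded, or no spectral peak rises a decade above
the median power (a straight, non-beating filament reports amplitude ≈ 0
with this flag rather than an error). No claim is made that these
operational definitions match any particular published table computed with
other estimators on real cells; on the generator they recover frequency to
one bin and amplitude and wavelength to within a few percent.

## Evaluation

`missed_detection_rate()` (MDR) is the percentage of baseline pixels
farther than `d` px from the test set; `false_detection_rate()` (FDR) the
percentage of test pixels farther than `d` from the baseline; `d = 3` by
default, reduced to 2 for 2× downsampled lanes (with ground truth rescaled
by the block-averaging coordinate map `x' = (x − 0.5)/k + 0.5`). Distances
are exact; the identities FDR(A,B,d) = MDR(B,A,d) and monotonicity in `d`
are enforced by tests against an all-pairs oracle. Published uses of these
metrics assess per-frame "success" by eye; that is not automatable, so a
frame counts as a success when its MDR and FDR are both ≤ 10%
(`success_mdr_max`, `success_fdr_max`) against ground truth. Aggregate
MDR/FDR pools pixels across frames; per-frame means are reported
alongside. Comparisons are between centerline pixel sets (traces), the
baseline being the phantom's rasterised true centerline.

Problem sizes used throughout the tests — 100-frame phantoms for the
recovery and degradation suites, 64-frame phantoms on a 3 × 3
amplitude × wavelength grid for kinematics, 100 random masks up to
64 × 64 for the transform oracle, 1000 random set pairs for the metric
properties — are the package's reference study conditions; the whole suite
runs in about a minute on one core.

## Numerical and degenerate-input choices

* Coordinates are 1-based `(row, col)` with pixel centers at integers; all
  widths are half-widths in pixels.
* An all-background mask has distance 0 everywhere; an all-foreground mask
  returns `Inf` (no background exists). Empty masks cannot be
  skeletonised.
* `binarize()` flags frames whose threshold yields under 1% or over 99%
  foreground as segmentation failures; the pipeline records such frames as
  `failed` and continues. Polarity is chosen as the phase touching fewer
  border pixels (a free swimmer is interior to the frame), with ties going
  to the minority phase.
* Ties are deterministic everywhere: modal bins break toward the smaller
  width, equal-size regions toward the lexicographically smallest pixel,
  equal stitching gaps and equal branch angles likewise. Reruns are
  bit-identical.
* A selected region of one pixel yields a one-point, zero-length trace
  flagged low-confidence, never an error; a free filament with no body
  yields a deterministic endpoint as attachment, also flagged.
* Frames are processed independently and streamed from multi-page TIFF
  one page at a time; only median background subtraction materialises the
  stack.

## Known limitations

* Near-tangential flagellar crossings can double the apparent width over
  an extended stretch; stitching cannot reliably repair these.
* Skeleton spurs are not pruned at the transform stage (pruning could
  delete a short flagellum); the longest-path rule handles them at
  tracing instead.
* The derivative method's sensitivity to its step size is inherent; it is
  provided for comparison, not as the default.
* Dense multi-cell scenes and ciliated epithelia are out of scope; the
  method addresses a single cell with one (possibly self-crossing)
  flagellum per frame.
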