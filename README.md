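# flagtrace

Fully-automated identification and tracing of eukaryotic flagella in
grayscale videomicroscopy of free-swimming cells.

Quantifying a flagellar beat from video normally requires manual tracing
or a heuristic tuned to one experiment, because the flagellum and the cell
body often share the same grey values and cannot be separated by
thresholding alone. `flagtrace` exploits a conserved morphological trait
instead: the 9+2 axoneme gives the flagellum an approximately constant
visible width, in contrast to the broader, more varied cell body. The
package is aimed at anyone tracking flagellated microswimmers —
trypanosomatids, spermatozoa, and similar single-flagellum cells — who
wants per-frame centerlines and beat parameters without per-frame input.

## Method

For each frame, with `M` the binary cell mask:

1. **Medial axis transform.** `MAT = D ⊙ S`, the pixel-wise product of the
   exact Euclidean distance map `D(p) = min{‖p − q‖ : q ∉ M}` and a
   connectivity-preserving skeleton `S` of `M` (sequential simple-point
   thinning; the skeleton of a connected region is connected). On the
   medial line, `MAT` is the local half-width of the cell in pixels.
2. **Modal width analysis.** A long flagellum of constant width dominates
   the mode of the width distribution. Skeleton pixels with
   `|MAT − w_mode| ≤ 1 px` form candidate regions; the largest connected
   candidate is the flagellum. Nearby fragments are re-joined by linear
   stitching bounded by the approximate flagellum width, and the
   attachment point is placed where the flagellar width plateau ends and
   the body widening begins. (A derivative analysis of the width profile —
   flagging the first outlier of a 3-step forward difference walked from
   the tip — is available as an alternative, but is less robust.)
3. **Tracing.** The selected region is ordered into a centerline from
   attachment to tip along the longest tangent-consistent path; at
   junctions the branch preserving the local tangent wins, so crossing
   filaments are traced straight through.

Evaluation uses the standard missed/false detection rates at distance
`d = 3 px`: MDR is the percentage of baseline pixels farther than `d` from
the test segmentation, FDR the percentage of test pixels farther than `d`
from the baseline. A built-in phantom generator provides beating-cell
videos with exact ground truth, plus the four classic degradations
(downsampling, Gaussian noise, Gaussian blur, illumination gradient) for
robustness benchmarking.

## Worked example

```r
library(flagtrace)

# a beating promastigote-like phantom: 29 Hz sine beat imaged at 200 Hz
ph <- make_phantom(phantom_params(n_frames = 100))
ph
#> phantom video: 100 frames of 80 x 140 px
#>   body 11.0 x 7.0 px (semi-axes), flagellum length 66.0 px, half-width 1.50 px
#>   beat: A = 4.30 px, lambda = 28.0 px, f = 29.0 Hz at 200 Hz

res <- run_pipeline(ph)
res
#> pipeline run: 100 frames (100 ok, 0 partial, 0 failed)
res[[1]]$trace
#> flagellum trace: 67 points, arclength 81.7 px

# compare traced centerlines against the exact ground truth at d = 3 px
truth <- lapply(ph$truth$centerline, rasterize_centerline)
evaluate_traces(lapply(res, function(f) f$trace), truth, d = 3)
#> segmentation evaluation over 100 frames (d = 3 px):
#>   pooled MDR 0.00%, FDR 0.00%; success rate 100.0%

# beat parameters at 0.3 um/px
beat_parameters(lapply(res, function(f) f$trace),
                frame_rate_hz = 200, pixel_size_um = 0.3)
#> flagellar beat parameters:
#>   dominant frequency  28.00 Hz
#>   wavelength          8.42 um
#>   amplitude           1.28 um
#>   flagellum length    25.15 um
#>   (100 frames used, 0 excluded)
```

Every frame is recovered (MDR/FDR 0% means every true centerline pixel is
within 3 px of the trace and vice versa). The beat is recovered at the
generator's settings: 28 Hz is within one spectral bin (200 Hz / 100
frames = 2 Hz) of the true 29 Hz, and the 8.42 µm wavelength and 1.28 µm
amplitude sit within a few percent of the generated 8.4 µm and 1.29 µm.
The traced length (25.2 µm) slightly exceeds the visible centerline
(~24 µm) because the trace follows the medial line into the
body–flagellum junction.

A command-line interface wraps the same functions
(`inst/cli/flagtrace`, subcommands `phantom`, `run`, `benchmark`,
`kinematics`, `eval`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/flagtrace", package="flagtrace"))')" \
    run --in movie.tif --out results/
```

writing per-frame traces and attachments as CSV, an overlay TIFF with the
centerline in white, and a run manifest.

## Vignette

`vignettes/flagellum-identification.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, what the
phantom generator does and does not emulate, numerical tie-breaking rules,
and known limitations.
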