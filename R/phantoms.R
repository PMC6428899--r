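#' Parameters for a synthetic flagellated-swimmer phantom
#'
#' Defines the geometry, beat and imaging parameters of a synthetic
#' grayscale video of a single flagellated cell: an elliptical body joined
#' to a slender flagellum of constant half-width, optionally beating as a
#' travelling sine wave. Defaults emulate promastigote-like morphology at a
#' scale of roughly 0.3 um/px: a 3 px visible flagellar width, a 66 px
#' flagellum on a 22 x 14 px body, beating at 29 Hz imaged at 200 Hz.
#'
#' The flagellar centerline is the parametric curve
#' `row(s, t) = r0 + A * sin(2*pi*s/lambda - 2*pi*f*t)`, `col(s) = c0 + s`,
#' for `s` in `[0, a + L]`, where `(r0, c0)` is the body center, `a` the
#' body semi-axis along the flagellar axis and `L = flagellum_length_px`
#' the extent of the flagellum beyond the body. The tube of half-width
#' `flagellum_halfwidth_px` around this curve passes through the body
#' center, so body and flagellum always form one connected region.
#'
#' @param image_height_px,image_width_px frame dimensions in pixels.
#' @param body_semi_axes_px length-2 numeric `(a, b)`: ellipse semi-axes in
#'   pixels, `a` along the flagellar (column) axis, `b` across it.
#' @param body_center_px length-2 numeric `(row, col)` body center.
#' @param flagellum_length_px extent of the flagellum beyond the body along
#'   the column axis, pixels.
#' @param flagellum_halfwidth_px half-width of the flagellar tube, pixels;
#'   must be at least 1 (visible width of at least 2-3 px) and strictly less
#'   than the smaller body semi-axis.
#' @param wave_amplitude_px,wave_wavelength_px,wave_frequency_hz travelling
#'   wave amplitude (px), wavelength (px) and temporal frequency (Hz).
#' @param frame_rate_hz,n_frames acquisition rate and number of frames.
#' @param foreground_intensity,background_intensity grey values in
#'   `[0, 255]` for cell and background pixels.
#' @param body_taper optional taper in `[0, 0.8]`: linearly shrinks the
#'   body's cross-axis semi-axis from the anterior to the flagellar pole,
#'   producing a harder, non-elliptic width profile. Default 0 (ellipse).
#' @param rng_seed integer seed recorded with the parameters (the generator
#'   itself is deterministic; the seed is used by noise degradations).
#'
#' @return An object of class `phantom_params`.
#' @seealso [make_phantom()], [degradation_spec()]
#' @export
phantom_params <- function(image_height_px = 80,
                           image_width_px = 140,
                           body_semi_axes_px = c(11, 7),
                           body_center_px = c(40, 30),
                           flagellum_length_px = 66,
                           flagellum_halfwidth_px = 1.5,
                           wave_amplitude_px = 4.3,
                           wave_wavelength_px = 28,
                           wave_frequency_hz = 29,
                           frame_rate_hz = 200,
                           n_frames = 100,
                           foreground_intensity = 200,
                           background_intensity = 10,
                           body_taper = 0,
                           rng_seed = 1L) {
  p <- list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    body_semi_axes_px = as.numeric(body_semi_axes_px),
    body_center_px = as.numeric(body_center_px),
    flagellum_length_px = as.numeric(flagellum_length_px),
    flagellum_halfwidth_px = as.numeric(flagellum_halfwidth_px),
    wave_amplitude_px = as.numeric(wave_amplitude_px),
    wave_wavelength_px = as.numeric(wave_wavelength_px),
    wave_frequency_hz = as.numeric(wave_frequency_hz),
    frame_rate_hz = as.numeric(frame_rate_hz),
    n_frames = as.integer(n_frames),
    foreground_intensity = as.numeric(foreground_intensity),
    background_intensity = as.numeric(background_intensity),
    body_taper = as.numeric(body_taper),
    rng_seed = as.integer(rng_seed)
  )
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  chk <- function(ok, what) if (!ok) stop("invalid phantom parameters: ", what)
  chk(p$image_height_px >= 1 && p$image_width_px >= 1,
      "image dimensions must be positive")
  chk(length(p$body_semi_axes_px) == 2 && all(p$body_semi_axes_px > 0),
      "body_semi_axes_px must be two positive values")
  chk(p$flagellum_length_px > 0, "flagellum_length_px must be positive")
  chk(p$flagellum_halfwidth_px >= 1,
      "flagellum_halfwidth_px must be >= 1 (visible width >= 2-3 px)")
  chk(p$flagellum_halfwidth_px < min(p$body_semi_axes_px),
      "flagellum_halfwidth_px must be < min(body_semi_axes_px) (body strictly wider than flagellum)")
  chk(p$wave_amplitude_px >= 0, "wave_amplitude_px must be non-negative")
  chk(p$wave_amplitude_px < p$body_semi_axes_px[2],
      "wave_amplitude_px must be < cross-axis body semi-axis (flagellum attaches at the body)")
  chk(p$wave_wavelength_px > 0, "wave_wavelength_px must be positive")
  chk(p$wave_frequency_hz >= 0, "wave_frequency_hz must be non-negative")
  chk(p$frame_rate_hz > 0, "frame_rate_hz must be positive")
  chk(p$n_frames >= 1, "n_frames must be a positive integer")
  chk(p$foreground_intensity >= 0 && p$foreground_intensity <= 255 &&
        p$background_intensity >= 0 && p$background_intensity <= 255,
      "intensities must lie in [0, 255]")
  chk(p$body_taper >= 0 && p$body_taper <= 0.8, "body_taper must lie in [0, 0.8]")
  invisible(p)
}

# Exact distance from every pixel center in a window to a polyline; pixels
# within `hw` of any segment are foreground. Polyline vertices approximate
# the continuous curve to well below rasterisation scale.
tube_mask <- function(H, W, verts, hw) {
  inside <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(verts) - 1L)) {
    p <- verts[i, ]; q <- verts[i + 1L, ]
    r0 <- max(1L, floor(min(p[1], q[1]) - hw)); r1 <- min(H, ceiling(max(p[1], q[1]) + hw))
    c0 <- max(1L, floor(min(p[2], q[2]) - hw)); c1 <- min(W, ceiling(max(p[2], q[2]) + hw))
    if (r0 > r1 || c0 > c1) next
    rows <- r0:r1; cols <- c0:c1
    R <- matrix(rows, length(rows), length(cols))
    C <- matrix(cols, length(rows), length(cols), byrow = TRUE)
    v <- q - p; L2 <- sum(v^2)
    t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((R - p[1]) * v[1] + (C - p[2]) * v[2]) / L2))
    d2 <- (R - (p[1] + t * v[1]))^2 + (C - (p[2] + t * v[2]))^2
    inside[rows, cols] <- inside[rows, cols] | (d2 <= hw^2 + 1e-9)
  }
  inside
}

#' Generate a synthetic phantom video with exact ground truth
#'
#' Rasterises the body-plus-flagellum phantom described by
#' [phantom_params()] into `n_frames` grayscale frames, recording per frame
#' the exact flagellar centerline, the attachment point, and disjoint body
#' and flagellum masks. A pixel is foreground iff its center lies within
#' the analytic region (ellipse, or tube of the centerline curve). The
#' generator is deterministic.
#'
#' @param params a [phantom_params()] object (or plain list with the same
#'   fields).
#' @return A list of class `phantom` with elements:
#' \describe{
#'   \item{frames}{list of `n_frames` numeric matrices with values in
#'     `[0, 255]`.}
#'   \item{truth}{list with `centerline` (per-frame matrix of real
#'     `(row, col)` coordinates of the flagellar medial line, ordered from
#'     attachment to tip), `attachment` (`n_frames x 2` matrix),
#'     `flagellum_mask` and `body_mask` (per-frame logical matrices,
#'     disjoint), and `halfwidth_px`.}
#'   \item{params}{the parameters used.}
#' }
#' @export
make_phantom <- function(params) {
  if (!inherits(params, "phantom_params")) params <- do.call(phantom_params, params)
  p <- params
  H <- p$image_height_px; W <- p$image_width_px
  a <- p$body_semi_axes_px[1]; b <- p$body_semi_axes_px[2]
  r0 <- p$body_center_px[1]; c0 <- p$body_center_px[2]
  hw <- p$flagellum_halfwidth_px
  A <- p$wave_amplitude_px; lam <- p$wave_wavelength_px; f <- p$wave_frequency_hz

  R <- matrix(seq_len(H), H, W)
  C <- matrix(seq_len(W), H, W, byrow = TRUE)
  # cross-axis semi-axis, optionally tapering toward the flagellar pole
  b_of <- function(cc) b * (1 - p$body_taper * pmin(1, pmax(0, (cc - (c0 - a)) / (2 * a))))
  body <- ((C - c0) / a)^2 + ((R - r0) / b_of(C))^2 <= 1

  s_r <- seq(0, a + p$flagellum_length_px, by = 0.5)   # rasterisation vertices
  s_t <- seq(0, a + p$flagellum_length_px, by = 0.25)  # truth samples

  frames <- vector("list", p$n_frames)
  centerline <- vector("list", p$n_frames)
  flagellum_mask <- vector("list", p$n_frames)
  body_mask <- vector("list", p$n_frames)
  attachment <- matrix(NA_real_, p$n_frames, 2, dimnames = list(NULL, c("row", "col")))

  for (i in seq_len(p$n_frames)) {
    t_i <- (i - 1) / p$frame_rate_hz
    curve_row <- function(s) r0 + A * sin(2 * pi * s / lam - 2 * pi * f * t_i)
    verts <- cbind(curve_row(s_r), c0 + s_r)
    tube <- tube_mask(H, W, verts, hw)
    cell <- body | tube
    fmask <- tube & !body

    pts <- cbind(row = curve_row(s_t), col = c0 + s_t)
    pr <- round(pts[, 1]); pc <- round(pts[, 2])
    inimg <- pr >= 1 & pr <= H & pc >= 1 & pc <= W
    inbody <- rep(TRUE, nrow(pts))
    inbody[inimg] <- body[cbind(pr[inimg], pc[inimg])]
    keep <- inimg & !inbody
    cl <- pts[keep, , drop = FALSE]

    frames[[i]] <- p$background_intensity +
      (p$foreground_intensity - p$background_intensity) * cell
    centerline[[i]] <- cl
    flagellum_mask[[i]] <- fmask
    body_mask[[i]] <- body
    if (nrow(cl)) attachment[i, ] <- cl[1, ]
  }

  structure(list(
    frames = frames,
    truth = list(centerline = centerline, attachment = attachment,
                 flagellum_mask = flagellum_mask, body_mask = body_mask,
                 halfwidth_px = hw),
    params = p
  ), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  p <- x$params
  cat(sprintf("phantom video: %d frames of %d x %d px\n",
              p$n_frames, p$image_height_px, p$image_width_px))
  cat(sprintf("  body %.1f x %.1f px (semi-axes), flagellum length %.1f px, half-width %.2f px\n",
              p$body_semi_axes_px[1], p$body_semi_axes_px[2],
              p$flagellum_length_px, p$flagellum_halfwidth_px))
  cat(sprintf("  beat: A = %.2f px, lambda = %.1f px, f = %.1f Hz at %.0f Hz\n",
              p$wave_amplitude_px, p$wave_wavelength_px, p$wave_frequency_hz,
              p$frame_rate_hz))
  invisible(x)
}

#' Rasterise a real-coordinate centerline to a connected pixel chain
#'
#' Rounds the ordered centerline samples to pixels and joins consecutive
#' pixels with rasterised straight segments, returning the unique pixels in
#' order. Used to turn ground-truth centerlines into pixel sets comparable
#' with traces.
#'
#' @param coords matrix of `(row, col)` coordinates (real-valued allowed).
#' @return integer matrix of unique `(row, col)` pixels.
#' @export
rasterize_centerline <- function(coords) {
  coords <- px_mat(coords)
  if (nrow(coords) == 0) return(coords)
  pr <- round(coords[, 1]); pc <- round(coords[, 2])
  pts <- cbind(row = pr, col = pc)
  pts <- pts[!duplicated(pts), , drop = FALSE]
  if (nrow(pts) == 1) return(pts)
  out <- list(pts[1, , drop = FALSE])
  for (i in 2:nrow(pts)) out[[i]] <- raster_segment(pts[i - 1, ], pts[i, ])[-1, , drop = FALSE]
  out <- do.call(rbind, out)
  out[!duplicated(out), , drop = FALSE]
}

#' Specification of a single image degradation
#'
#' Describes one of the four degradations used in the robustness benchmark:
#' block-average downsampling, additive Gaussian noise (sd on the 0-255
#' scale) with clipping, isotropic Gaussian blur, or pixel-wise blending
#' with a black-to-white horizontal gradient emulating non-uniform
#' illumination. Parameters irrelevant to the chosen kind are ignored.
#'
#' @param kind one of `"downsample"`, `"gaussian_noise"`, `"gaussian_blur"`,
#'   `"gradient_blend"`.
#' @param factor positive integer downsampling factor per spatial dimension.
#' @param noise_sd standard deviation of the additive noise, grey levels.
#' @param blur_radius_px Gaussian blur radius (standard deviation), pixels.
#' @param rng_seed integer seed making the noise degradation deterministic.
#' @return An object of class `degradation_spec`.
#' @export
degradation_spec <- function(kind = c("downsample", "gaussian_noise",
                                      "gaussian_blur", "gradient_blend"),
                             factor = 2L, noise_sd = 10, blur_radius_px = 2,
                             rng_seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "downsample" && (length(factor) != 1 || is.na(factor) ||
                               factor < 1 || factor != round(factor)))
    stop("downsampling `factor` must be a positive integer")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (blur_radius_px < 0) stop("`blur_radius_px` must be non-negative")
  structure(list(kind = kind, factor = as.integer(factor),
                 noise_sd = as.numeric(noise_sd),
                 blur_radius_px = as.numeric(blur_radius_px),
                 rng_seed = as.integer(rng_seed)),
            class = "degradation_spec")
}

#' Apply a single image degradation to a grayscale frame
#'
#' @param frame numeric matrix with values in `[0, 255]`.
#' @param spec a [degradation_spec()].
#' @return The degraded frame. Downsampling reduces each dimension by
#'   `factor` via block averaging (trailing rows/columns that do not fill a
#'   block are dropped); noise is i.i.d. zero-mean Gaussian, clipped to
#'   `[0, 255]` and deterministic given `rng_seed`; blur convolves with an
#'   isotropic Gaussian of standard deviation `blur_radius_px` (replicated
#'   boundary); gradient blending multiplies by a horizontal ramp from 0
#'   (left) to 1 (right).
#' @export
degrade <- function(frame, spec) {
  stopifnot(inherits(spec, "degradation_spec"), is.matrix(frame))
  switch(spec$kind,
    downsample = block_downsample(frame, spec$factor),
    gaussian_noise = {
      if (spec$noise_sd == 0) frame
      else {
        noisy <- frame + with_seed(spec$rng_seed,
                                   matrix(rnorm(length(frame), 0, spec$noise_sd),
                                          nrow(frame), ncol(frame)))
        pmin(pmax(noisy, 0), 255)
      }
    },
    gaussian_blur = {
      if (spec$blur_radius_px == 0) frame
      else EBImage::gblur(frame, sigma = spec$blur_radius_px, boundary = "replicate")
    },
    gradient_blend = {
      ramp <- if (ncol(frame) == 1) matrix(1, nrow(frame), 1)
              else matrix((seq_len(ncol(frame)) - 1) / (ncol(frame) - 1),
                          nrow(frame), ncol(frame), byrow = TRUE)
      frame * ramp
    }
  )
}

block_downsample <- function(frame, k) {
  if (k == 1) return(frame)
  H <- (nrow(frame) %/% k) * k
  W <- (ncol(frame) %/% k) * k
  if (H < k || W < k) stop("frame too small for downsampling factor ", k)
  m <- frame[seq_len(H), seq_len(W), drop = FALSE]
  m <- matrix(colMeans(matrix(m, nrow = k)), H %/% k, W)       # rows
  m <- t(matrix(colMeans(matrix(t(m), nrow = k)), W %/% k, H %/% k))  # cols
  m
}

#' Rescale ground-truth coordinates after downsampling
#'
#' Maps 1-based pixel-center coordinates of the original image to the
#' coordinate frame of an image block-downsampled by integer `factor`:
#' `x' = (x - 0.5) / factor + 0.5`.
#'
#' @param coords matrix of `(row, col)` coordinates.
#' @param factor integer downsampling factor.
#' @return rescaled coordinate matrix.
#' @export
scale_coords <- function(coords, factor) {
  coords <- px_mat(coords)
  (coords - 0.5) / factor + 0.5
}

#' Write a phantom to disk (multi-page TIFF plus truth CSV and JSON sidecar)
#'
#' @param phantom a [make_phantom()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written: `frames.tif` (8-bit grayscale),
#'   `centerline.csv` with columns `frame, index, row, col`, and
#'   `params.json` echoing the generator parameters and per-frame
#'   attachment points.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tif <- file.path(dir, "frames.tif")
  tiff::writeTIFF(lapply(phantom$frames, function(m) m / 255), tif,
                  bits.per.sample = 8)
  cl <- do.call(rbind, lapply(seq_along(phantom$truth$centerline), function(i) {
    m <- phantom$truth$centerline[[i]]
    if (!nrow(m)) return(NULL)
    data.frame(frame = i, index = seq_len(nrow(m)), row = m[, 1], col = m[, 2])
  }))
  csv <- file.path(dir, "centerline.csv")
  write.csv(cl, csv, row.names = FALSE)
  js <- file.path(dir, "params.json")
  jsonlite::write_json(list(params = unclass(phantom$params),
                            halfwidth_px = phantom$truth$halfwidth_px,
                            attachment = phantom$truth$attachment),
                       js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(frames = tif, centerline = csv, params = js))
}
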