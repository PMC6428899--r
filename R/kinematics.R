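# Beat-parameter extraction from a time series of flagellum traces:
# dominant temporal frequency, wavelength, amplitude and flagellar length.

#' Beat parameters from a sequence of flagellum traces
#'
#' Summarises per-frame centerline traces into the parameters of a
#' travelling-wave beat `y(x, t) = A sin(k x - 2 pi f t + phi)`:
#'
#' * Traces are aligned to a common body frame: the origin is the mean
#'   attachment point (or per-frame body centroid when `body_masks` are
#'   given) and the x-axis is the principal axis of the pooled trace
#'   points, oriented from attachment toward the tips.
#' * The dominant frequency is the peak of the Hann-windowed periodogram of
#'   the transverse displacement at the trace midpoint (the point nearest
#'   the middle of the common x-range), excluding the zero-frequency bin.
#' * The amplitude is `sqrt(2)` times the RMS of that transverse signal
#'   (exact for a pure sinusoid).
#' * The wavelength is `2 pi / k` from a least-squares fit of
#'   `a sin(k x) + b cos(k x)` per frame, profiled over `k`.
#' * The flagellar length is the mean trace arclength.
#'
#' Results are flagged low confidence when fewer than two beat periods are
#' covered, when frames had to be excluded, or when no spectral peak rises
#' above the noise floor (e.g. a non-beating flagellum).
#'
#' @param traces list of `flagellum_trace` objects (or `NULL` for failed
#'   frames, which are excluded and counted).
#' @param frame_rate_hz acquisition frame rate.
#' @param pixel_size_um physical pixel size; 1 reports lengths in pixels.
#' @param body_masks optional list of body masks for per-frame centroid
#'   alignment.
#' @return object of class `beat_parameters` with fields
#'   `dominant_frequency_hz`, `wavelength_um`, `amplitude_um`,
#'   `flagellum_length_um`, `pixel_size_um`, `frame_rate_hz`,
#'   `n_frames_used`, `n_excluded`, `low_confidence`.
#' @export
beat_parameters <- function(traces, frame_rate_hz, pixel_size_um = 1,
                            body_masks = NULL) {
  ok <- vapply(traces, function(t_) inherits(t_, "flagellum_trace") &&
                 nrow(t_$points) >= 5, logical(1))
  n_excluded <- sum(!ok)
  used <- which(ok)
  if (length(used) < 8) stop("too few usable traces for beat analysis")
  tr <- traces[used]

  att <- do.call(rbind, lapply(tr, function(t_) as.numeric(t_$attachment$point)))
  pooled <- do.call(rbind, lapply(tr, function(t_) t_$points))
  origin <- if (!is.null(body_masks)) {
    cm <- do.call(rbind, lapply(body_masks[used], function(m) {
      px <- which(m, arr.ind = TRUE)
      c(mean(px[, 1]), mean(px[, 2]))
    }))
    colMeans(cm)
  } else colMeans(att)

  cen <- sweep(pooled, 2, origin)
  ax <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)$vectors[, 1]
  # orient the axis from attachment toward the flagellar tips
  tips <- do.call(rbind, lapply(tr, function(t_) t_$points[nrow(t_$points), ]))
  if (mean((tips[, 1] - origin[1]) * ax[1] + (tips[, 2] - origin[2]) * ax[2]) < 0)
    ax <- -ax
  perp <- c(-ax[2], ax[1])

  bodyframe <- lapply(tr, function(t_) {
    p <- sweep(t_$points, 2, origin)
    cbind(x = p[, 1] * ax[1] + p[, 2] * ax[2],
          y = p[, 1] * perp[1] + p[, 2] * perp[2])
  })

  # transverse displacement at the common-x midpoint
  xmin <- max(vapply(bodyframe, function(b) min(b[, "x"]), numeric(1)))
  xmax <- min(vapply(bodyframe, function(b) max(b[, "x"]), numeric(1)))
  if (xmax <= xmin) { xmin <- min(pooled[, 2]); xmax <- max(pooled[, 2]) }
  xmid <- (xmin + xmax) / 2
  ymid <- vapply(bodyframe, function(b) b[which.min(abs(b[, "x"] - xmid)), "y"],
                 numeric(1))
  ymid <- ymid - mean(ymid)
  amplitude_px <- sqrt(2) * sqrt(mean(ymid^2))

  n <- length(ymid)
  low_conf <- n_excluded > 0
  if (var(ymid) < 1e-8) {
    freq <- 0
    low_conf <- TRUE
  } else {
    hann <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
    p <- Mod(fft(ymid * hann))^2
    half <- p[2:(floor(n / 2) + 1)]
    kpk <- which.max(half)
    freq <- kpk * frame_rate_hz / n
    if (max(half) < 10 * median(half)) low_conf <- TRUE
    if (n / frame_rate_hz < 2 / freq) low_conf <- TRUE
  }

  # profile least-squares over the wavenumber of a single-harmonic fit
  rss_k <- function(k) {
    sum(vapply(bodyframe, function(b) {
      X <- cbind(sin(k * b[, "x"]), cos(k * b[, "x"]))
      y <- b[, "y"]
      fit <- tryCatch(qr.fitted(qr(X), y), error = function(e) rep(mean(y), length(y)))
      sum((y - fit)^2)
    }, numeric(1)))
  }
  span <- xmax - xmin
  lams <- seq(max(6, span / 20), 4 * max(span, 10), length.out = 160)
  rss <- vapply(2 * pi / lams, rss_k, numeric(1))
  lam0 <- lams[which.min(rss)]
  opt <- optimize(function(l) rss_k(2 * pi / l),
                  interval = c(max(lam0 * 0.7, 4), lam0 * 1.4))
  wavelength_px <- opt$minimum

  len_px <- mean(vapply(tr, function(t_) t_$length_px, numeric(1)))

  structure(list(
    dominant_frequency_hz = freq,
    wavelength_um = wavelength_px * pixel_size_um,
    amplitude_um = amplitude_px * pixel_size_um,
    flagellum_length_um = len_px * pixel_size_um,
    pixel_size_um = pixel_size_um,
    frame_rate_hz = frame_rate_hz,
    n_frames_used = n,
    n_excluded = n_excluded,
    low_confidence = low_conf
  ), class = "beat_parameters")
}

#' @export
print.beat_parameters <- function(x, ...) {
  u <- if (x$pixel_size_um == 1) "px" else "um"
  cat("flagellar beat parameters",
      if (x$low_confidence) " [low confidence]" else "", ":\n", sep = "")
  cat(sprintf("  dominant frequency  %.2f Hz\n", x$dominant_frequency_hz))
  cat(sprintf("  wavelength          %.2f %s\n", x$wavelength_um, u))
  cat(sprintf("  amplitude           %.2f %s\n", x$amplitude_um, u))
  cat(sprintf("  flagellum length    %.2f %s\n", x$flagellum_length_um, u))
  cat(sprintf("  (%d frames used, %d excluded)\n", x$n_frames_used, x$n_excluded))
  invisible(x)
}

#' Beat parameters as a one-row table (or CSV)
#'
#' @param bp a `beat_parameters` object.
#' @param path optional CSV output path.
#' @return one-row data frame.
#' @export
beat_parameters_table <- function(bp, path = NULL) {
  stopifnot(inherits(bp, "beat_parameters"))
  df <- data.frame(dominant_frequency_hz = bp$dominant_frequency_hz,
                   wavelength_um = bp$wavelength_um,
                   amplitude_um = bp$amplitude_um,
                   flagellum_length_um = bp$flagellum_length_um,
                   pixel_size_um = bp$pixel_size_um,
                   frame_rate_hz = bp$frame_rate_hz,
                   n_frames_used = bp$n_frames_used,
                   n_excluded = bp$n_excluded,
                   low_confidence = bp$low_confidence)
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
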