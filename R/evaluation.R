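# Segmentation evaluation: missed detection rate (MDR) and false detection
# rate (FDR) between pixel sets, and the degradation benchmark harness.

# Exact minimum Euclidean distance from each pixel in `from` to the set `to`,
# chunked to bound memory.
min_dist_to_set <- function(from, to) {
  from <- px_mat(from); to <- px_mat(to)
  n <- nrow(from)
  out <- numeric(n)
  chunk <- max(1L, floor(4e6 / nrow(to)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d2 <- outer(from[s:e, 1], to[, 1], "-")^2 + outer(from[s:e, 2], to[, 2], "-")^2
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Missed detection rate
#'
#' The percentage of baseline pixels lying more than `d` pixels (Euclidean)
#' from the test segmentation: the proportion of the true region the test
#' implementation failed to identify. An empty test set misses everything
#' (100).
#'
#' @param test,baseline pixel sets as `(row, col)` matrices (real-valued
#'   coordinates allowed).
#' @param d distance tolerance in pixels; 3 by default.
#' @return percentage in `[0, 100]`.
#' @export
missed_detection_rate <- function(test, baseline, d = 3) {
  baseline <- px_mat(baseline)
  if (!nrow(baseline)) stop("`baseline` must be non-empty")
  test <- px_mat(test)
  if (!nrow(test)) return(100)
  100 * mean(min_dist_to_set(baseline, test) > d + 1e-9)
}

#' False detection rate
#'
#' The percentage of test pixels lying more than `d` pixels from the
#' baseline: the prevalence of falsely identified regions. Dual to
#' [missed_detection_rate()]: `FDR(A, B, d) == MDR(B, A, d)`.
#'
#' @inheritParams missed_detection_rate
#' @return percentage in `[0, 100]`.
#' @export
false_detection_rate <- function(test, baseline, d = 3) {
  test <- px_mat(test)
  if (!nrow(test)) stop("`test` must be non-empty")
  baseline <- px_mat(baseline)
  if (!nrow(baseline)) return(100)
  100 * mean(min_dist_to_set(test, baseline) > d + 1e-9)
}

as_px_set <- function(x) {
  if (is.null(x)) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  if (inherits(x, "flagellum_trace")) return(px_mat(x$points))
  px_mat(x)
}

#' Evaluate per-frame segmentations against a baseline
#'
#' Computes per-frame and pooled MDR/FDR of a list of test pixel sets (or
#' `flagellum_trace`s) against baseline pixel sets, plus a per-frame success
#' flag (frame MDR and FDR both at or below configurable maxima — the
#' automatable stand-in for by-eye assessment). Pooled rates count pixels
#' across all frames; per-frame means are also reported.
#'
#' @param test,baseline lists (one element per frame) of pixel sets; test
#'   entries may be `NULL` (failed frames, counted as fully missed).
#' @param d distance tolerance in pixels.
#' @param success_mdr_max,success_fdr_max per-frame success thresholds in
#'   percent (default 10 each).
#' @return object of class `eval_report`: `mdr_percent`, `fdr_percent`
#'   (pooled), `mdr_mean_percent`, `fdr_mean_percent` (per-frame means),
#'   `success_rate_percent`, `d_px`, `n_frames`, and a `per_frame` data
#'   frame.
#' @export
evaluate_traces <- function(test, baseline, d = 3,
                            success_mdr_max = 10, success_fdr_max = 10) {
  stopifnot(length(test) == length(baseline), length(test) >= 1)
  n <- length(test)
  per <- data.frame(frame = seq_len(n), mdr = NA_real_, fdr = NA_real_,
                    success = FALSE)
  missed <- 0; nbase <- 0; false_ <- 0; ntest <- 0
  for (i in seq_len(n)) {
    b <- as_px_set(baseline[[i]])
    t_ <- as_px_set(test[[i]])
    if (!nrow(b)) next  # no ground truth for this frame
    nbase <- nbase + nrow(b)
    if (!nrow(t_)) {
      per$mdr[i] <- 100
      missed <- missed + nrow(b)
      next
    }
    db <- min_dist_to_set(b, t_)
    dt <- min_dist_to_set(t_, b)
    per$mdr[i] <- 100 * mean(db > d + 1e-9)
    per$fdr[i] <- 100 * mean(dt > d + 1e-9)
    missed <- missed + sum(db > d + 1e-9)
    false_ <- false_ + sum(dt > d + 1e-9)
    ntest <- ntest + nrow(t_)
    per$success[i] <- per$mdr[i] <= success_mdr_max && per$fdr[i] <= success_fdr_max
  }
  structure(list(
    mdr_percent = if (nbase) 100 * missed / nbase else NA_real_,
    fdr_percent = if (ntest) 100 * false_ / ntest else NA_real_,
    mdr_mean_percent = mean(per$mdr, na.rm = TRUE),
    fdr_mean_percent = mean(per$fdr, na.rm = TRUE),
    success_rate_percent = 100 * mean(per$success[!is.na(per$mdr)]),
    d_px = d, n_frames = n, per_frame = per
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("segmentation evaluation over %d frames (d = %g px):\n", x$n_frames, x$d_px))
  cat(sprintf("  pooled MDR %.2f%%, FDR %.2f%%; success rate %.1f%%\n",
              x$mdr_percent, x$fdr_percent, x$success_rate_percent))
  invisible(x)
}

#' Degradation robustness benchmark on a phantom video
#'
#' Applies each image degradation to every frame of a phantom, runs the full
#' identification pipeline on the degraded frames, and evaluates the traced
#' centerlines against the phantom's ground-truth centerline. For
#' downsampled lanes the ground truth is rescaled with [scale_coords()] and
#' the distance tolerance is reduced to 2 px for 2x and kept at 3 px for 4x
#' downsampling, accounting for the loss of resolution. Failed frames count
#' against the success rate; no degradation aborts the benchmark.
#'
#' @param phantom a [make_phantom()] result.
#' @param specs list of [degradation_spec()]s; a clean (undegraded) lane is
#'   always included first.
#' @param config a [pipeline_config()].
#' @return data frame with one row per lane (`degradation`, `mdr_percent`,
#'   `fdr_percent`, `success_rate_percent`, `n_frames`, `d_px`); full
#'   `eval_report`s are attached as attribute `"reports"`.
#' @export
run_degradation_benchmark <- function(phantom, specs, config = pipeline_config()) {
  stopifnot(inherits(phantom, "phantom"))
  truth_px <- lapply(phantom$truth$centerline, rasterize_centerline)
  lanes <- c(list(clean = NULL), stats::setNames(specs, vapply(specs, function(s) {
    switch(s$kind,
           downsample = sprintf("downsample_%dx", s$factor),
           gaussian_noise = sprintf("gaussian_noise_sd%g", s$noise_sd),
           gaussian_blur = sprintf("gaussian_blur_r%g", s$blur_radius_px),
           gradient_blend = "gradient_blend")
  }, character(1))))
  rows <- list(); reports <- list()
  for (nm in names(lanes)) {
    spec <- lanes[[nm]]
    frames <- phantom$frames
    base <- truth_px
    d <- config$d_px
    if (!is.null(spec)) {
      frames <- lapply(frames, degrade, spec = spec)
      if (spec$kind == "downsample") {
        base <- lapply(phantom$truth$centerline,
                       function(cl) rasterize_centerline(scale_coords(cl, spec$factor)))
        d <- if (spec$factor <= 2) 2 else 3
      }
    }
    res <- run_pipeline(frames, config)
    traces <- lapply(res, function(fr) if (is.null(fr$trace)) NULL else fr$trace)
    rep <- evaluate_traces(traces, base, d = d,
                           success_mdr_max = config$success_mdr_max,
                           success_fdr_max = config$success_fdr_max)
    reports[[nm]] <- rep
    rows[[nm]] <- data.frame(degradation = nm,
                             mdr_percent = rep$mdr_percent,
                             fdr_percent = rep$fdr_percent,
                             success_rate_percent = rep$success_rate_percent,
                             n_frames = rep$n_frames, d_px = d)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}
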