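#' Background subtraction for a frame stack
#'
#' Estimates a per-pixel background and removes it from every frame. With
#' more than one frame the background is the temporal median image (static
#' scene content cancels; a moving cell survives). With a single frame a
#' flat field equal to the modal grey level is used. The residuals are
#' jointly rescaled to `[0, 255]` across the stack so inter-frame contrast
#' is preserved; an all-zero residual stack (static scene) is returned as
#' zeros.
#'
#' Intended for recordings with static background clutter. Synthetic
#' phantoms and clean recordings can skip this step (the default pipeline
#' does, see [pipeline_config()]).
#'
#' @param stack list of numeric matrices of identical dimensions.
#' @return list of matrices of the same shape, values in `[0, 255]`.
#' @export
subtract_background <- function(stack) {
  if (is.matrix(stack)) stack <- list(stack)
  if (length(stack) == 0) stop("empty frame stack")
  dims <- dim(stack[[1]])
  if (!all(vapply(stack, function(f) identical(dim(f), dims), logical(1))))
    stop("all frames must have identical dimensions")
  if (length(stack) > 1) {
    arr <- array(unlist(stack), dim = c(dims, length(stack)))
    bg <- apply(arr, c(1, 2), median)
  } else {
    v <- round(as.vector(stack[[1]]))
    bg <- matrix(as.numeric(names(which.max(table(v)))), dims[1], dims[2])
  }
  res <- lapply(stack, function(f) f - bg)
  rng <- range(unlist(lapply(res, range)))
  if (diff(rng) < .Machine$double.eps)
    return(lapply(res, function(f) matrix(0, dims[1], dims[2])))
  lapply(res, function(f) (f - rng[1]) / diff(rng) * 255)
}

# Otsu threshold via EBImage; `frame` values can be on any scale.
otsu_threshold <- function(frame) {
  rng <- range(frame)
  if (diff(rng) < .Machine$double.eps)
    flag_failure("constant frame: no foreground to segment",
                 "flagtrace_segmentation_failure")
  EBImage::otsu(frame, range = rng, levels = 256L)
}

#' Binarise a background-corrected frame into a single-cell mask
#'
#' Thresholds the frame with an automatic histogram (Otsu) threshold,
#' chooses the cell polarity as the phase touching fewer image-border
#' pixels (a free-swimming cell lies interior to the frame; ties go to the
#' minority phase), then cleans up: foreground specks smaller than
#' `min_object_area_px` are removed, interior background holes smaller than
#' `fill_hole_area_px` are filled, and the largest 8-connected foreground
#' component is kept.
#'
#' Frames in which thresholding yields less than 1\% or more than 99\%
#' foreground are rejected with a segmentation-failure condition (class
#' `"flagtrace_segmentation_failure"`), which [run_pipeline()] contains as
#' a failed frame.
#'
#' @param frame numeric matrix (any grey scale).
#' @param min_object_area_px remove foreground components smaller than this
#'   area in pixels; default 9.
#' @param fill_hole_area_px fill interior background components smaller
#'   than this area; default 9.
#' @param threshold_method currently `"otsu"`.
#' @return logical matrix with exactly one 8-connected foreground component
#'   (the cell).
#' @export
binarize <- function(frame, min_object_area_px = 9, fill_hole_area_px = 9,
                     threshold_method = "otsu") {
  threshold_method <- match.arg(threshold_method, "otsu")
  th <- otsu_threshold(frame)
  phase <- frame > th

  border <- function(m) sum(m[1, ]) + sum(m[nrow(m), ]) + sum(m[, 1]) + sum(m[, ncol(m)])
  bA <- border(phase); bB <- border(!phase)
  fg <- if (bA != bB) {
    if (bA < bB) phase else !phase
  } else if (sum(phase) <= sum(!phase)) phase else !phase

  frac <- mean(fg)
  if (frac < 0.01 || frac > 0.99)
    flag_failure(sprintf("segmentation failure: foreground fraction %.3f outside [0.01, 0.99]", frac),
                 "flagtrace_segmentation_failure")

  # remove small foreground specks
  lab <- cpp_label_components(fg, 8L)
  sizes <- tabulate(lab)
  if (any(sizes < min_object_area_px))
    fg[lab %in% which(sizes < min_object_area_px)] <- FALSE
  if (!any(fg))
    flag_failure("segmentation failure: no foreground left after speck removal",
                 "flagtrace_segmentation_failure")

  # fill small interior holes (4-connected background not touching border)
  hol <- cpp_label_components(!fg, 4L)
  border_labels <- unique(c(hol[1, ], hol[nrow(hol), ], hol[, 1], hol[, ncol(hol)]))
  hsizes <- tabulate(hol)
  fill <- setdiff(which(hsizes < fill_hole_area_px), border_labels)
  if (length(fill)) fg[hol %in% fill] <- TRUE

  # keep the largest component (first-encountered label wins ties)
  lab <- cpp_label_components(fg, 8L)
  sizes <- tabulate(lab)
  fg <- lab == which.max(sizes)
  fg
}
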