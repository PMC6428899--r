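#' Exact Euclidean distance map of a binary mask
#'
#' For every foreground pixel, the exact Euclidean distance (in pixels) to
#' the nearest background pixel; 0 on background. This is the width half of
#' the medial axis transform: along the medial line it equals the local
#' half-width of the shape.
#'
#' @param mask logical (or 0/1 numeric) matrix.
#' @return numeric matrix of distances. A mask with no background pixels
#'   returns `Inf` on the (all-)foreground.
#' @export
euclidean_distance_map <- function(mask) {
  mask <- check_mask(mask)
  if (!any(mask)) return(matrix(0, nrow(mask), ncol(mask)))
  if (all(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(mask * 1, metric = "euclidean")
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

#' Connectivity-preserving skeletonisation
#'
#' Thins each 8-connected foreground component to a unit-width medial curve
#' by sequential deletion of simple points (border pixels whose removal
#' preserves local topology) in alternating directional sub-passes, with
#' endpoints preserved. Deleting only simple points guarantees that the
#' skeleton of a connected region is itself connected and that holes are
#' preserved (an annulus thins to a closed loop). Foreground uses
#' 8-connectivity, background 4-connectivity.
#'
#' Short spurs are not pruned at this stage; spur handling is a tracing
#' concern (see [resolve_branches()]).
#'
#' @param mask logical (or 0/1 numeric) matrix with at least one foreground
#'   pixel.
#' @return logical matrix marking skeleton pixels.
#' @export
skeletonize_connected <- function(mask) {
  mask <- check_mask(mask)
  if (!any(mask)) stop("cannot skeletonize an empty mask")
  cpp_thin(mask)
}

#' Medial axis transform of a binary mask
#'
#' The pixel-wise product of the exact Euclidean distance map and a
#' connectivity-preserving skeletonisation: nonzero only on skeleton
#' pixels, where the value is the local half-width of the shape in pixels.
#' Regions of greater width map to points of greater magnitude along the
#' medial line.
#'
#' @param mask logical (or 0/1 numeric) matrix with at least one foreground
#'   pixel.
#' @return An object of class `medial_axis_map`: a list with `values`
#'   (numeric matrix, nonzero only on the skeleton), `skeleton` (logical
#'   matrix), and `distance` (the full distance map).
#' @export
medial_axis_transform <- function(mask) {
  mask <- check_mask(mask)
  sk <- skeletonize_connected(mask)
  dm <- euclidean_distance_map(mask)
  structure(list(values = dm * sk, skeleton = sk, distance = dm),
            class = "medial_axis_map")
}

#' @export
print.medial_axis_map <- function(x, ...) {
  n <- sum(x$skeleton)
  cat(sprintf("medial axis transform: %d x %d image, %d skeleton pixels\n",
              nrow(x$values), ncol(x$values), n))
  if (n) {
    w <- x$values[x$skeleton]
    cat(sprintf("  half-width range %.2f - %.2f px (median %.2f)\n",
                min(w), max(w), median(w)))
  }
  invisible(x)
}

#' Skeleton pixels as a coordinate matrix
#'
#' @param x a `medial_axis_map` or logical skeleton matrix.
#' @return integer matrix of `(row, col)` skeleton pixels in column-major
#'   order.
#' @export
skeleton_pixels <- function(x) {
  sk <- if (inherits(x, "medial_axis_map")) x$skeleton else check_mask(x)
  which(sk, arr.ind = TRUE, useNames = FALSE) |>
    (\(m) matrix(m, ncol = 2, dimnames = list(NULL, c("row", "col"))))()
}

#' Skeleton endpoints (pixels with at most one skeleton neighbour)
#'
#' @param skeleton logical matrix.
#' @return integer matrix of `(row, col)` endpoints.
#' @export
skeleton_endpoints <- function(skeleton) {
  skeleton <- if (inherits(skeleton, "medial_axis_map")) skeleton$skeleton
              else check_mask(skeleton)
  nb <- count_neighbors(skeleton)
  ep <- skeleton & nb <= 1
  which(ep, arr.ind = TRUE, useNames = FALSE) |>
    (\(m) matrix(m, ncol = 2, dimnames = list(NULL, c("row", "col"))))()
}

#' Write a medial axis transform as a floating-point TIFF
#'
#' Debug output: stores `values / max(values)` as a 32-bit float TIFF (the
#' TIFF writer expects `[0, 1]`); the scale factor is returned so the
#' half-widths can be recovered.
#'
#' @param mat a `medial_axis_map`.
#' @param path output file path.
#' @return Invisibly, the maximum half-width used as the scale factor.
#' @export
write_mat_tiff <- function(mat, path) {
  stopifnot(inherits(mat, "medial_axis_map"))
  mx <- max(mat$values)
  if (mx == 0) mx <- 1
  tiff::writeTIFF(mat$values / mx, path, bits.per.sample = 32L)
  invisible(mx)
}
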