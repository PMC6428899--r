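# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Structured failure conditions: per-frame algorithm failures are signalled
# with class "flagtrace_failure" so the pipeline can contain them, while
# programming errors remain ordinary errors.
flag_failure <- function(message, class = "flagtrace_failure") {
  stop(structure(
    class = c(class, "flagtrace_failure", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# Coerce a pixel set to an integer matrix with columns (row, col).
px_mat <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("row", "col")])
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  x <- matrix(as.numeric(x), ncol = 2, dimnames = list(NULL, c("row", "col")))
  x
}

# Deterministic lexicographic order of (row, col) pixels.
px_order <- function(px) order(px[, 1], px[, 2])

px_key <- function(px, H) px[, 1] + (px[, 2] - 1) * H

# Logical mask from a pixel set.
px_to_mask <- function(px, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[cbind(px[, 1], px[, 2])] <- TRUE
  m
}

# Count of foreground 8-neighbours for every pixel, vectorised via shifts.
count_neighbors <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  p <- matrix(0L, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- mask
  n <- matrix(0L, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    n <- n + p[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  }
  n
}

# Pixels of a rasterised straight segment between two pixels (Bresenham-like
# supercover by rounding along the longer axis); includes both endpoints.
raster_segment <- function(p, q) {
  n <- max(abs(q - p)) + 1
  if (n == 1) return(matrix(p, ncol = 2, dimnames = list(NULL, c("row", "col"))))
  t <- seq(0, 1, length.out = n)
  px <- cbind(row = round(p[1] + t * (q[1] - p[1])),
              col = round(p[2] + t * (q[2] - p[2])))
  px[!duplicated(px), , drop = FALSE]
}

# Order candidate regions by size (desc), ties broken toward the region
# containing the lexicographically smallest pixel; pick the largest region
# of at least `min_region_px` pixels (fall back to the largest overall,
# flagged low confidence).
order_regions <- function(regions, min_region_px) {
  sizes <- vapply(regions, nrow, integer(1))
  minr <- vapply(regions, function(r) min(r[, 1]), numeric(1))
  minc <- vapply(regions, function(r) {
    rr <- r[r[, 1] == min(r[, 1]), , drop = FALSE]
    min(rr[, 2])
  }, numeric(1))
  ord <- order(-sizes, minr, minc)
  regions <- regions[ord]
  sizes <- sizes[ord]
  pick <- which(sizes >= min_region_px)[1]
  low_conf <- is.na(pick)
  if (low_conf) pick <- 1L
  list(regions = regions, pick = pick, low_confidence = low_conf)
}

# Validate a binary mask argument.
check_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) stop(sprintf("`%s` must be a matrix", arg))
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.logical(mask)) stop(sprintf("`%s` must be logical or numeric", arg))
  mask[is.na(mask)] <- FALSE
  mask
}
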