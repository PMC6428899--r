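# Shared fixtures and independent oracles. Everything is generated in code;
# expensive objects are cached for the duration of the test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# The reference phantom: the package's default study conditions.
ref_phantom <- function(n_frames = 100) {
  cached(paste0("phantom_", n_frames),
         make_phantom(phantom_params(n_frames = n_frames)))
}

ref_results <- function(n_frames = 100) {
  cached(paste0("results_", n_frames),
         run_pipeline(ref_phantom(n_frames), pipeline_config()))
}

ref_truth_px <- function(n_frames = 100) {
  cached(paste0("truthpx_", n_frames),
         lapply(ref_phantom(n_frames)$truth$centerline, rasterize_centerline))
}

# Brute-force exact Euclidean distance map: O(fg x bg) scan.
brute_edt <- function(m) {
  bg <- which(!m, arr.ind = TRUE)
  fg <- which(m, arr.ind = TRUE)
  out <- matrix(0, nrow(m), ncol(m))
  if (nrow(fg) && nrow(bg)) {
    for (i in seq_len(nrow(fg)))
      out[fg[i, 1], fg[i, 2]] <-
        sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
  }
  out
}

# Brute-force minimum distance from each row of `a` to the set `b`.
brute_min_dists <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i)
    sqrt(min((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2)), numeric(1))
}

# Canonical shapes (shape dimensions chosen so the skeleton has structure).
shape_disk <- function(r = 10, pad = 10) {
  n <- 2 * (r + pad)
  m <- matrix(FALSE, n, n)
  (row(m) - n / 2)^2 + (col(m) - n / 2)^2 <= r^2
}

shape_annulus <- function(r_out = 15, r_in = 8, pad = 6) {
  n <- 2 * (r_out + pad)
  m <- matrix(FALSE, n, n)
  d2 <- (row(m) - n / 2)^2 + (col(m) - n / 2)^2
  d2 <= r_out^2 & d2 >= r_in^2
}

shape_triangle <- function() {
  m <- matrix(FALSE, 60, 70)
  R <- row(m); C <- col(m)
  side <- function(p1, p2) (p2[1] - p1[1]) * (C - p1[2]) - (p2[2] - p1[2]) * (R - p1[1])
  s1 <- side(c(10, 10), c(50, 10)); s2 <- side(c(50, 10), c(30, 65)); s3 <- side(c(30, 65), c(10, 10))
  (s1 >= 0 & s2 >= 0 & s3 >= 0) | (s1 <= 0 & s2 <= 0 & s3 <= 0)
}

# Two straight unit-width skeletons crossing at ~90 degrees.
shape_crossing <- function() {
  sk <- matrix(FALSE, 50, 50)
  sk[25, 5:45] <- TRUE
  sk[5:45, 22] <- TRUE
  sk
}

# Random blob mask: union of random disks (plus optional speckle).
random_blob_mask <- function(h, w, n_blobs = 4) {
  m <- matrix(FALSE, h, w)
  R <- row(m); C <- col(m)
  for (b in seq_len(n_blobs)) {
    r0 <- runif(1, 1, h); c0 <- runif(1, 1, w); rad <- runif(1, 1, min(h, w) / 3)
    m <- m | ((R - r0)^2 + (C - c0)^2 <= rad^2)
  }
  m
}

px_order_test <- function(px) order(px[, 1], px[, 2])

attachment_errors <- function(results, phantom) {
  vapply(seq_along(results), function(i) {
    tr <- results[[i]]$trace
    if (is.null(tr)) return(Inf)
    sqrt(sum((tr$attachment$point - phantom$truth$attachment[i, ])^2))
  }, numeric(1))
}
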