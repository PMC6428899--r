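test_that("distance map matches the brute-force oracle on random masks", {
  set.seed(101)
  for (rep in 1:25) {
    h <- sample(8:32, 1); w <- sample(8:32, 1)
    m <- if (rep %% 2) matrix(runif(h * w) < runif(1, 0.2, 0.8), h, w)
         else random_blob_mask(h, w)
    if (!any(m)) m[1, 1] <- TRUE
    if (all(m)) m[1, 1] <- FALSE
    expect_equal(euclidean_distance_map(m), brute_edt(m), tolerance = 0)
  }
})

test_that("distance map degenerate inputs", {
  expect_equal(euclidean_distance_map(matrix(FALSE, 5, 5)), matrix(0, 5, 5))
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_equal(euclidean_distance_map(m)[3, 3], 1)
  expect_true(all(is.infinite(euclidean_distance_map(matrix(TRUE, 4, 4)))))
})

test_that("unit-width input is its own skeleton", {
  bar <- matrix(FALSE, 10, 20); bar[5, 3:17] <- TRUE
  expect_identical(skeletonize_connected(bar), bar)
  diag <- matrix(FALSE, 15, 15); diag[cbind(3:12, 3:12)] <- TRUE
  expect_identical(skeletonize_connected(diag), diag)
  expect_error(skeletonize_connected(matrix(FALSE, 4, 4)), "empty")
})

test_that("a filled disk maps to a small central cluster encoding its radius", {
  mat <- medial_axis_transform(shape_disk(r = 10))
  px <- skeleton_pixels(mat)
  expect_lte(nrow(px), 4)
  # mutually adjacent cluster
  if (nrow(px) > 1) {
    d <- as.matrix(dist(px))
    expect_lte(max(d), sqrt(2) + 1e-9)
  }
  expect_gte(max(mat$values), 9)
  expect_lte(max(mat$values), 11)
})

test_that("an annulus maps to one closed loop of near-constant width", {
  mat <- medial_axis_transform(shape_annulus(r_out = 15, r_in = 8))
  sk <- mat$skeleton
  expect_equal(max(flagtrace:::cpp_label_components(sk, 8L)), 1)
  expect_equal(nrow(skeleton_endpoints(sk)), 0)  # closed loop
  w <- mat$values[sk]
  expect_lte(max(w) - min(w), 2)  # constant to within +/- 1 px
  # ring half-thickness (15 - 8) / 2 = 3.5 encoded along the loop
  expect_lt(abs(median(w) - 3.5), 1)
})

test_that("a triangle's width decreases along branches toward the corners", {
  mat <- medial_axis_transform(shape_triangle())
  sk <- mat$skeleton
  eps <- skeleton_endpoints(sk)
  expect_gte(nrow(eps), 2)
  # walk from each endpoint toward the center: widths must rise monotonely
  # (allowing the transform's rasterisation jitter of 1 px)
  for (i in seq_len(nrow(eps))) {
    path <- resolve_branches(sk, eps[i, ])
    n <- min(15, nrow(path$points))
    w <- mat$values[path$points[1:n, , drop = FALSE]]
    run_max <- cummax(w)
    expect_true(all(w >= run_max - 1))
    expect_gt(w[n], w[1])
  }
})

test_that("transform values equal exact distances on skeleton pixels", {
  set.seed(77)
  for (rep in 1:10) {
    m <- random_blob_mask(40, 40)
    if (!any(m)) next
    if (all(m)) m[1, 1] <- FALSE
    mat <- medial_axis_transform(m)
    d <- brute_edt(m)
    expect_equal(mat$values, d * mat$skeleton, tolerance = 0)
  }
})

test_that("skeletonisation preserves component count and topology", {
  set.seed(303)
  for (rep in 1:15) {
    m <- matrix(runif(30 * 30) < runif(1, 0.3, 0.7), 30, 30)
    if (!any(m)) next
    sk <- skeletonize_connected(m)
    expect_equal(max(flagtrace:::cpp_label_components(sk, 8L)),
                 max(flagtrace:::cpp_label_components(m, 8L)))
    expect_true(all(m[sk]))  # skeleton within the mask
  }
})

test_that("the skeleton's width disks cover the shapes the method targets", {
  # reconstruction bound on cell-like and canonical shapes (convex corners
  # of arbitrary blobs are deliberately not covered: spur-free thinning
  # prunes corner ridges so that a disk maps to a single point)
  ph <- make_phantom(phantom_params(n_frames = 2))
  shapes <- list(ph$truth$body_mask[[1]] | ph$truth$flagellum_mask[[1]],
                 ph$truth$body_mask[[2]] | ph$truth$flagellum_mask[[2]],
                 shape_disk(r = 10), shape_annulus())
  for (m in shapes) {
    mat <- medial_axis_transform(m)
    fg <- which(m, arr.ind = TRUE)
    sk <- skeleton_pixels(mat)
    vals <- mat$values[sk]
    covered <- vapply(seq_len(nrow(fg)), function(i) {
      d <- sqrt((sk[, 1] - fg[i, 1])^2 + (sk[, 2] - fg[i, 2])^2)
      any(d <= vals + 1.5)
    }, logical(1))
    expect_true(all(covered))
  }
})

test_that("skeletons of blob masks are unit width", {
  set.seed(21)
  for (rep in 1:10) {
    m <- random_blob_mask(40, 40)
    if (!any(m)) next
    if (all(m)) m[1, 1] <- FALSE
    sk <- skeletonize_connected(m)
    two_by_two <- sk[-nrow(sk), -ncol(sk)] & sk[-1, -ncol(sk)] &
      sk[-nrow(sk), -1] & sk[-1, -1]
    expect_equal(sum(two_by_two), 0)
  }
})
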