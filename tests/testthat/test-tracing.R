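test_that("stitching joins nearby collinear segments and respects the radius", {
  r1 <- cbind(row = rep(10, 10), col = 1:10)
  r2 <- cbind(row = rep(10, 10), col = 14:23)   # 3-px gap (endpoints 10 and 14)
  st <- stitch_segments(list(r1, r2), radius_px = 6)
  expect_length(st$regions, 1)
  expect_length(st$bridges, 1)
  merged <- st$regions[[1]]
  expect_true(all(c(11, 12, 13) %in% merged[merged[, 1] == 10, 2]))

  far <- cbind(row = rep(10, 10), col = 31:40)  # 20-px gap
  st2 <- stitch_segments(list(r1, far), radius_px = 6)
  expect_length(st2$regions, 2)
  expect_length(st2$bridges, 0)

  # single region is returned unchanged
  st3 <- stitch_segments(list(r1), radius_px = 6)
  expect_length(st3$regions, 1)
  expect_equal(st3$regions[[1]], flagtrace:::px_mat(r1))
})

test_that("stitching on a clean segmentation changes nothing", {
  ph <- ref_phantom(100)
  mask <- binarize(ph$frames[[7]])
  mat <- medial_axis_transform(mask)
  res <- modal_segment(mat)
  st <- stitch_segments(res$candidate_regions, radius_px = 2 * res$modal_width,
                        dim = dim(mask))
  expect_length(st$bridges, 0)
  expect_length(st$regions, length(res$candidate_regions))
})

test_that("branch resolution walks straight through a 90-degree crossing", {
  sk <- shape_crossing()
  ph <- resolve_branches(sk, c(25, 5))
  expect_true(all(ph$points[, 1] == 25))
  expect_equal(nrow(ph$points), 41)
  pv <- resolve_branches(sk, c(5, 22))
  expect_true(all(pv$points[, 2] == 22))
  expect_equal(nrow(pv$points), 41)
})

test_that("branch resolution prefers the tangent-aligned branch at a Y junction", {
  sk <- matrix(FALSE, 60, 60)
  sk[30, 5:30] <- TRUE
  for (i in 1:25) sk[30 - round(i * tan(10 * pi / 180)), 30 + i] <- TRUE  # 10 deg
  for (i in 1:12) {
    r <- 30 - round(i * tan(80 * pi / 180))
    if (r >= 1) sk[r, 30 + i] <- TRUE                                     # 80 deg
  }
  p <- resolve_branches(sk, c(30, 5))
  endp <- unname(p$points[nrow(p$points), ])
  expect_equal(endp[2], 55)               # reached the far end of the 10-deg arm
  expect_lte(abs(endp[1] - 26), 1)
})

test_that("branch resolution on a simple path equals the naive ordering", {
  stair <- matrix(FALSE, 20, 20)
  stair[cbind(c(4:10, rep(10, 6)), c(rep(4, 7), 5:10))] <- TRUE
  p <- resolve_branches(stair, c(4, 4))
  expect_equal(nrow(p$points), sum(stair))
  expect_false(any(duplicated(p$points)))
  expect_error(resolve_branches(stair, c(10, 5)), "endpoint")
  expect_error(resolve_branches(stair, c(1, 1)), "skeleton pixel")
})

test_that("phantom traces match ground truth in length and geometry", {
  ph <- ref_phantom(100)
  res <- ref_results(100)
  for (i in c(1, 33, 66, 99)) {
    tr <- res[[i]]$trace
    cl <- ph$truth$centerline[[i]]
    truth_len <- sum(sqrt(rowSums(diff(cl)^2)))
    expect_lt(abs(tr$length_px - truth_len) / truth_len, 0.05)
    # every trace point within 1.5 px of the true centerline
    d <- brute_min_dists(tr$points, cl)
    expect_lte(max(d), 1.5)
    # ordered attachment -> tip
    expect_lt(sum((tr$points[1, ] - ph$truth$attachment[i, ])^2), 25)
  }
})

test_that("degenerate single-pixel selection yields a flagged one-point trace", {
  sk <- matrix(FALSE, 10, 10); sk[5, 5] <- TRUE
  v <- sk * 2
  mat <- structure(list(values = v, skeleton = sk, distance = v),
                   class = "medial_axis_map")
  res <- modal_segment(mat, min_region_px = 5)
  expect_true(res$low_confidence)
  att <- attachment_from_modal(res, mat)
  tr <- trace_flagellum(res, att, mat)
  expect_equal(nrow(tr$points), 1)
  expect_equal(tr$length_px, 0)
  expect_true(tr$low_confidence)
})

test_that("a disconnected selection is traced partially from the attachment side", {
  sk <- matrix(FALSE, 20, 60)
  sk[10, 5:25] <- TRUE; sk[10, 40:55] <- TRUE
  v <- sk * 2
  mat <- structure(list(values = v, skeleton = sk, distance = v),
                   class = "medial_axis_map")
  res <- modal_segment(mat)
  # force both pieces into one "selected" set, as if stitching had failed
  res$selected <- skeleton_pixels(sk)
  att <- flagtrace:::new_attachment_estimate(c(10, 5), 0, "modal")
  tr <- trace_flagellum(res, att, mat)
  expect_true(tr$partial)
  expect_equal(sort(unique(tr$points[, 2])), 5:25)
})
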