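test_that("width profile follows arclength with the 1/sqrt(2) step rule", {
  bar <- matrix(FALSE, 10, 20); bar[5, 3:12] <- TRUE
  mat <- medial_axis_transform(bar)
  prof <- extract_width_profile(mat)
  expect_equal(prof$arclength, 0:9)
  expect_equal(length(prof$widths), 10)

  stair <- matrix(FALSE, 15, 15); stair[cbind(3:10, 3:10)] <- TRUE
  mats <- medial_axis_transform(stair)
  profs <- extract_width_profile(mats)
  expect_equal(max(profs$arclength), 7 * sqrt(2))
})

test_that("width profile rejects branched skeletons and bad starts", {
  sk <- matrix(FALSE, 20, 20)
  sk[10, 3:17] <- TRUE; sk[3:9, 10] <- TRUE  # T junction
  mat <- list(values = sk * 1, skeleton = sk, distance = sk * 1)
  class(mat) <- "medial_axis_map"
  expect_error(extract_width_profile(mat), "resolve")
  bar <- matrix(FALSE, 10, 20); bar[5, 3:12] <- TRUE
  matb <- medial_axis_transform(bar)
  expect_error(extract_width_profile(matb, start = c(5, 7)), "endpoint")
})

test_that("phantom width profile shows a flagellar plateau rising into the body", {
  ph <- make_phantom(phantom_params(n_frames = 1, wave_amplitude_px = 0,
                                    flagellum_halfwidth_px = 3,
                                    body_semi_axes_px = c(11, 7),
                                    image_height_px = 90))
  mask <- binarize(ph$frames[[1]])
  mat <- medial_axis_transform(mask)
  res <- modal_segment(mat)
  att <- attachment_from_modal(res, mat)
  tr <- trace_flagellum(res, att, mat)
  # plateau: interior widths near the true half-width of 3
  w <- tr$widths_px[5:(length(tr$widths_px) - 5)]
  expect_true(all(abs(w - 3) <= 1))
  # the full profile from the flagellar tip rises into the body
  tip <- tr$points[nrow(tr$points), ]
  path <- resolve_branches(mat$skeleton, tip)
  wfull <- mat$values[path$points]
  expect_gt(max(wfull), 5)
})

test_that("width histogram finds the modal bin with ties toward thin", {
  h <- width_histogram(c(3, 3, 3, 3, 8, 9, 10), bin_width = 1)
  expect_equal(h$modal_width, 3)
  expect_equal(h$modal_width_refined, 3)
  # constant widths: single occupied bin
  h2 <- width_histogram(rep(4.2, 10), bin_width = 1)
  expect_equal(h2$modal_width, 4)
  expect_equal(h2$modal_width_refined, 4.2)
  # tie between counts -> smaller width wins
  h3 <- width_histogram(c(2, 2, 2, 7, 7, 7), bin_width = 1)
  expect_equal(h3$modal_width, 2)
})

test_that("modal segmentation selects the largest near-modal region", {
  # synthetic transform: a 40-px region and a 12-px region at width 2,
  # separated by a wide stretch
  sk <- matrix(FALSE, 30, 80)
  sk[15, 2:75] <- TRUE
  v <- matrix(0, 30, 80)
  v[15, 2:41] <- 2          # 40 px at flagellar width
  v[15, 42:63] <- 8         # body-like stretch
  v[15, 64:75] <- 2         # 12 px at flagellar width
  mat <- structure(list(values = v, skeleton = sk, distance = v),
                   class = "medial_axis_map")
  res <- modal_segment(mat, tolerance = 1)
  expect_equal(res$modal_width, 2)
  expect_equal(nrow(res$selected), 40)
  expect_equal(length(res$candidate_regions), 2)
  expect_equal(sort(unique(res$selected[, 2])), 2:41)

  # uniform-width skeleton: one candidate covering everything
  v2 <- (sk * 1) * 2
  mat2 <- structure(list(values = v2, skeleton = sk, distance = v2),
                    class = "medial_axis_map")
  res2 <- modal_segment(mat2)
  expect_equal(length(res2$candidate_regions), 1)
  expect_equal(nrow(res2$selected), sum(sk))

  # nothing within tolerance is impossible by construction of the mode, but
  # an empty transform must fail loudly
  expect_error(modal_segment(structure(list(values = v * 0, skeleton = sk & FALSE,
                                            distance = v * 0),
                                       class = "medial_axis_map")),
               "empty")
})

test_that("modal segmentation is invariant to translation and rotation", {
  ph <- make_phantom(phantom_params(n_frames = 1))
  mask <- ph$truth$body_mask[[1]] | ph$truth$flagellum_mask[[1]]
  res0 <- modal_segment(medial_axis_transform(mask))
  # translation: embed in a larger canvas with an offset
  big <- matrix(FALSE, 100, 170)
  big[11:90, 21:160] <- mask
  res1 <- modal_segment(medial_axis_transform(big))
  expect_equal(res1$modal_width, res0$modal_width)
  sel0 <- res0$selected[px_order_test(res0$selected), ]
  sel1 <- res1$selected[px_order_test(res1$selected), ]
  expect_equal(sel1 - cbind(rep(10, nrow(sel1)), rep(20, nrow(sel1))), sel0)
  # 90-degree rotation: widths are geometric, so the modal width and region
  # agree up to the thinning's directional tie-breaks (sub-pixel effects)
  rot <- t(mask)[ncol(mask):1, ]
  res2 <- modal_segment(medial_axis_transform(rot))
  expect_lt(abs(res2$modal_width - res0$modal_width), 0.05)
  expect_lte(abs(nrow(res2$selected) - nrow(res0$selected)), 2)
})

test_that("upscaling a mask scales the modal width accordingly", {
  ph <- make_phantom(phantom_params(n_frames = 1))
  mask <- ph$truth$body_mask[[1]] | ph$truth$flagellum_mask[[1]]
  res1 <- modal_segment(medial_axis_transform(mask))
  k <- 2
  up <- mask[rep(seq_len(nrow(mask)), each = k), rep(seq_len(ncol(mask)), each = k)]
  resk <- modal_segment(medial_axis_transform(up))
  expect_lt(abs(resk$modal_width - k * res1$modal_width), k + 1)
})

test_that("derivative analysis flags a width step change near its location", {
  n <- 60
  pts <- cbind(row = rep(5, n), col = seq_len(n))
  prof <- structure(list(points = pts, arclength = as.numeric(0:(n - 1)),
                         widths = c(rep(2, 40), rep(6, 20))),
                    class = "width_profile")
  att <- derivative_segment(prof, step = 3)
  expect_equal(att$method, "derivative")
  expect_lte(abs(att$point[2] - 40), 3)  # within `step` of the jump

  # monotone-constant profile: no body, identification failure
  prof2 <- structure(list(points = pts, arclength = as.numeric(0:(n - 1)),
                          widths = rep(2, n)), class = "width_profile")
  expect_error(derivative_segment(prof2), class = "flagtrace_identification_failure")
  # too-short profile
  prof3 <- structure(list(points = pts[1:8, ], arclength = as.numeric(0:7),
                          widths = rep(2, 8)), class = "width_profile")
  expect_error(derivative_segment(prof3), class = "flagtrace_identification_failure")
})

test_that("modal attachment lands on the body side", {
  ph <- ref_phantom(100)
  errs <- attachment_errors(ref_results(100), ph)
  expect_gte(mean(errs <= 3), 0.95)

  # symmetric free filament: deterministic endpoint, low confidence, no error
  bar <- matrix(FALSE, 10, 40); bar[5, 3:37] <- TRUE
  mat <- medial_axis_transform(bar)
  res <- modal_segment(mat)
  att <- attachment_from_modal(res, mat)
  expect_true(att$low_confidence)
  expect_equal(att$point, c(5, 3))

  # region touching the image border: the interior endpoint adjoining wider
  # skeleton is preferred
  m <- matrix(FALSE, 20, 60)
  m[10, 1:40] <- TRUE           # filament starts at the border
  m[5:15, 41:55] <- TRUE        # body block on the interior side
  mat2 <- medial_axis_transform(m)
  res2 <- modal_segment(mat2)
  att2 <- attachment_from_modal(res2, mat2)
  expect_gt(att2$point[2], 20)  # attachment on the body side, not the border
})
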