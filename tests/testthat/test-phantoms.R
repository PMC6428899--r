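test_that("phantom parameters are validated with named constraints", {
  expect_error(phantom_params(flagellum_halfwidth_px = 0.5), "flagellum_halfwidth_px")
  expect_error(phantom_params(flagellum_halfwidth_px = 8), "body_semi_axes")
  expect_error(phantom_params(wave_amplitude_px = 7.5), "wave_amplitude_px")
  expect_error(phantom_params(n_frames = 0), "n_frames")
  expect_error(phantom_params(foreground_intensity = 300), "intensities")
})

test_that("zero-amplitude flagellum rasterises as an exact stadium", {
  p <- phantom_params(n_frames = 1, wave_amplitude_px = 0,
                      flagellum_halfwidth_px = 2)
  ph <- make_phantom(p)
  a <- p$body_semi_axes_px[1]
  r0 <- p$body_center_px[1]; c0 <- p$body_center_px[2]
  m <- ph$truth$flagellum_mask[[1]]
  # analytic stadium: within halfwidth of the segment from the body center
  # out to s = a + L at row r0, minus the body ellipse
  R <- row(m); C <- col(m)
  t <- pmin(pmax((C - c0) / (a + p$flagellum_length_px), 0), 1)
  px <- c0 + t * (a + p$flagellum_length_px)
  d2 <- (R - r0)^2 + (C - px)^2
  body <- ((C - c0) / a)^2 + ((R - r0) / p$body_semi_axes_px[2])^2 <= 1
  expect_identical(m, d2 <= p$flagellum_halfwidth_px^2 + 1e-9 & !body)
  # centerline is a straight horizontal segment
  cl <- ph$truth$centerline[[1]]
  expect_true(all(cl[, 1] == r0))
  expect_true(all(diff(cl[, 2]) > 0))
})

test_that("body and flagellum form one 8-connected component, masks disjoint", {
  ph <- ref_phantom(100)
  for (i in c(1, 25, 50, 88)) {
    cell <- ph$truth$body_mask[[i]] | ph$truth$flagellum_mask[[i]]
    lab <- flagtrace:::cpp_label_components(cell, 8L)
    expect_equal(max(lab), 1)
    expect_false(any(ph$truth$body_mask[[i]] & ph$truth$flagellum_mask[[i]]))
    # rasterised centerline lies in the flagellum mask
    clpx <- rasterize_centerline(ph$truth$centerline[[i]])
    expect_true(all(cell[clpx]))
    frac_in <- mean(ph$truth$flagellum_mask[[i]][clpx])
    expect_gt(frac_in, 0.9)
  }
})

test_that("straight flagellum centerline pixels sit ~halfwidth from background", {
  # centerline off the pixel grid, so rasterisation does not sit exactly on
  # the tube boundary
  p <- phantom_params(n_frames = 1, wave_amplitude_px = 0,
                      flagellum_halfwidth_px = 3, body_semi_axes_px = c(11, 7),
                      body_center_px = c(40.3, 30))
  ph <- make_phantom(p)
  cell <- ph$truth$body_mask[[1]] | ph$truth$flagellum_mask[[1]]
  d <- brute_edt(cell)
  cl <- rasterize_centerline(ph$truth$centerline[[1]])
  # away from tip and attachment the tube is locally a band of half-width 3
  interior <- cl[cl[, 2] > min(cl[, 2]) + 5 & cl[, 2] < max(cl[, 2]) - 5, ]
  vals <- d[interior]
  expect_true(all(vals >= 2.5 & vals <= 3.5))

  # grid-aligned centerline: boundary pixels at exactly the half-width are
  # foreground (center-in-region rule), so the distance is halfwidth + 1
  p2 <- phantom_params(n_frames = 1, wave_amplitude_px = 0,
                       flagellum_halfwidth_px = 3, body_semi_axes_px = c(11, 7))
  ph2 <- make_phantom(p2)
  cell2 <- ph2$truth$body_mask[[1]] | ph2$truth$flagellum_mask[[1]]
  d2 <- brute_edt(cell2)
  cl2 <- rasterize_centerline(ph2$truth$centerline[[1]])
  interior2 <- cl2[cl2[, 2] > min(cl2[, 2]) + 5 & cl2[, 2] < max(cl2[, 2]) - 5, ]
  expect_true(all(d2[interior2] == 4))
})

test_that("phantom generation is deterministic", {
  p <- phantom_params(n_frames = 3)
  ph1 <- make_phantom(p); ph2 <- make_phantom(p)
  expect_identical(ph1$frames, ph2$frames)
  expect_identical(ph1$truth$centerline, ph2$truth$centerline)
})

test_that("modal width of a long flagellum phantom matches the halfwidth", {
  # mode dominance: flagellum length >= 3 x max body semi-axis
  for (hw in c(1.5, 2, 3)) {
    p <- phantom_params(n_frames = 1, flagellum_halfwidth_px = hw,
                        body_semi_axes_px = c(11, 7), flagellum_length_px = 66,
                        image_height_px = 90)
    ph <- make_phantom(p)
    cell <- ph$truth$body_mask[[1]] | ph$truth$flagellum_mask[[1]]
    d <- brute_edt(cell)
    cl <- rasterize_centerline(ph$truth$centerline[[1]])
    h <- width_histogram(d[cl][d[cl] > 0], bin_width = 1)
    expect_lte(abs(h$modal_width - round(hw)), 1)
  }
})

test_that("degradations behave per contract", {
  fr <- matrix(runif(136 * 76, 0, 255), 136, 76)
  # 136 x 76 downsampled 4x -> 34 x 19
  expect_equal(dim(degrade(fr, degradation_spec("downsample", factor = 4))), c(34, 19))
  # block averaging: mean preserved exactly
  expect_equal(mean(degrade(fr, degradation_spec("downsample", factor = 4))), mean(fr))
  # zero noise is the identity
  expect_identical(degrade(fr, degradation_spec("gaussian_noise", noise_sd = 0)), fr)
  # noise is deterministic given the seed and clipped
  n1 <- degrade(fr, degradation_spec("gaussian_noise", noise_sd = 10, rng_seed = 3))
  n2 <- degrade(fr, degradation_spec("gaussian_noise", noise_sd = 10, rng_seed = 3))
  expect_identical(n1, n2)
  expect_true(all(n1 >= 0 & n1 <= 255))
  expect_false(identical(n1, degrade(fr, degradation_spec("gaussian_noise", rng_seed = 4))))
  # blur of a constant field is the same constant
  const <- matrix(80, 40, 30)
  expect_equal(degrade(const, degradation_spec("gaussian_blur", blur_radius_px = 2)),
               const, tolerance = 1e-6)
  # gradient blend: left column to zero, right column unchanged
  g <- degrade(const, degradation_spec("gradient_blend"))
  expect_equal(g[, 1], rep(0, 40))
  expect_equal(g[, 30], rep(80, 40))
  expect_error(degradation_spec("downsample", factor = 0), "positive integer")
})

test_that("downsampling scales ground-truth coordinates by 1/k", {
  ph <- ref_phantom(100)
  k <- 2
  fr2 <- degrade(ph$frames[[1]], degradation_spec("downsample", factor = k))
  cl2 <- scale_coords(ph$truth$centerline[[1]], k)
  # scaled centerline must land on the downsampled cell: check intensities
  px <- rasterize_centerline(cl2)
  inb <- px[, 1] >= 1 & px[, 1] <= nrow(fr2) & px[, 2] >= 1 & px[, 2] <= ncol(fr2)
  vals <- fr2[px[inb, , drop = FALSE]]
  expect_gt(mean(vals > 100), 0.95)
})

test_that("phantom writer produces TIFF, CSV and JSON sidecar", {
  dir <- withr::local_tempdir()
  ph <- make_phantom(phantom_params(n_frames = 2))
  paths <- write_phantom(ph, dir)
  expect_true(all(file.exists(paths)))
  pages <- tiff::readTIFF(paths["frames"], all = TRUE)
  expect_length(pages, 2)
  expect_equal(dim(pages[[1]]), c(80, 140))
  cl <- read.csv(paths["centerline"])
  expect_named(cl, c("frame", "index", "row", "col"))
  js <- jsonlite::read_json(paths["params"])
  expect_equal(js$params$n_frames, 2)
})
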