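test_that("a uniform image yields a constant profile at every width", {
  img <- matrix(7, 50, 50)
  axis <- cbind(x = seq(10, 40), y = rep(25, 31))
  p1 <- extract_wide_line_profile(img, axis, width_px = 1)
  p20 <- extract_wide_line_profile(img, axis, width_px = 20)
  expect_true(all(abs(p1 - 7) < 1e-9))
  expect_true(all(abs(p20 - 7) < 1e-9))
})

test_that("width does not matter on a transversely uniform band", {
  img <- matrix(0, 60, 60)
  img[, 20:40] <- rep(seq(1, 21), each = 60)   # varies along x only
  axis <- cbind(x = seq(22, 38), y = rep(30, 17))
  p1 <- extract_wide_line_profile(img, axis, width_px = 1)
  p15 <- extract_wide_line_profile(img, axis, width_px = 15)
  expect_equal(p1, p15, tolerance = 1e-6)
})

test_that("the membrane profile of a noiseless cell peaks at the two poles", {
  sc <- single_cell_scene(length_um = 3.0)
  img <- sc$stack$data[1, 1, , ]
  ax <- medial_axis_of(segment_frame(img) == 1)
  prof <- extract_wide_line_profile(img, ax, 20)
  n <- length(prof)
  top <- which(prof > max(prof) * 0.9)
  expect_true(any(top <= n / 4) && any(top >= 3 * n / 4))
  expect_error(extract_wide_line_profile(img, cbind(1, 1), 20), "shorter")
})

test_that("cell length is the medial-axis arc length times the pixel size", {
  axis <- cbind(x = seq(0, 45), y = rep(0, 46))
  expect_equal(measure_cell_length(axis, 0.065), 45 * 0.065)
  sc <- single_cell_scene(length_um = 3.0)
  ax <- medial_axis_of(segment_frame(sc$stack$data[1, 1, , ]) == 1)
  expect_lt(abs(measure_cell_length(ax, 0.065) - 3.0), 2 * 0.065)
})

test_that("nucleoid length sums contiguous detectable runs and is 0 when undetectable", {
  bg <- list(level = 100, sigma = 2)
  expect_equal(measure_nucleoid_length(rep(100, 50), bg, 0.065), 0)
  prof <- rep(100, 50); prof[11:30] <- 400
  expect_equal(measure_nucleoid_length(prof, bg, 0.065), 20 * 0.065)
  # two rendered 0.5 um segments -> 1.0 um total within +-2 px
  sc <- single_cell_scene(length_um = 3.0,
                          segments = rbind(c(0.5, 1.0), c(2.0, 2.5)))
  lab <- segment_frame(sc$stack$data[1, 1, , ])
  ax <- medial_axis_of(lab == 1)
  nb <- estimate_background(sc$stack$data[1, 2, , ], lab)
  pn <- extract_wide_line_profile(sc$stack$data[1, 2, , ], ax, 20)
  expect_lt(abs(measure_nucleoid_length(pn, nb, 0.065) - 1.0), 2 * 0.065)
})

test_that("nucleoid intensity is background-corrected and linear", {
  img <- matrix(100, 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[5:15, 5:15] <- TRUE
  bg <- list(level = 100, sigma = 1)
  expect_equal(measure_nucleoid_intensity(mask, img, bg), 0)
  img[mask] <- 150
  v1 <- measure_nucleoid_intensity(mask, img, bg)
  img[mask] <- 200
  expect_equal(measure_nucleoid_intensity(mask, img, bg), 2 * v1)
})

test_that("normalisation fixes the treatment-start frame at 100 and is idempotent", {
  expect_equal(normalize_series(c(2, 3, 4), 1), c(100, 150, 200))
  expect_equal(normalize_series(rep(5, 4), 2), rep(100, 4))
  x <- c(80, 100, 130)
  expect_equal(normalize_series(normalize_series(x, 2), 2),
               normalize_series(x, 2))
  expect_error(normalize_series(c(0, 1, 2), 1), "un-normalizable")
})

test_that("the nucleoid/cell ratio is clipped to [0,1] with the 0-when-undetectable rule", {
  expect_equal(ratio_series(1.5, 3.0), 0.5)
  expect_equal(ratio_series(0, 3.0), 0)
  expect_equal(ratio_series(4, 3.0), 1)
  expect_true(is.na(ratio_series(1, 0)))
})

test_that("kymograph columns follow growth and the loss of nucleoid signal", {
  run <- noiseless_run("dmso_control")
  ana <- run$analysis
  stack <- render_timelapse(run$trajectories)$stack
  ks <- analysis_kymographs(ana, stack, cell_ids = ana$cell_ids[1])
  km <- ks[[1]]$membrane
  bg <- 100 + 30
  extents <- colSums(km > bg)
  expect_true(all(diff(extents[3:23]) >= 0))   # growing cell: extent rises
  expect_gt(extents[23], extents[3] * 1.5)
  # column extent matches the measured length within ~1 px
  f <- subset(ana$features, cell_id == ana$cell_ids[1])
  expect_true(all(abs(extents - f$length_um / 0.065) <= 3))

  # a CCCP cell's nucleoid channel collapses to background after onset
  runc <- noiseless_run("cccp")
  stackc <- render_timelapse(runc$trajectories)$stack
  ksc <- analysis_kymographs(runc$analysis, stackc,
                             cell_ids = runc$analysis$cell_ids[1])
  kn <- ksc[[1]]$nucleoid
  pre <- mean(kn[kn[, 3] > 0, 3])
  post <- kn[, 23]
  expect_lt(max(post), 100 + 0.2 * (pre - 100))
})

test_that("a single-frame track yields a one-column kymograph equal to its profile", {
  sc <- single_cell_scene()
  lab <- segment_frame(sc$stack$data[1, 1, , ])
  ax <- medial_axis_of(lab == 1)
  track <- list(present = c(TRUE, rep(FALSE, 22)),
                axes = c(list(ax), vector("list", 22)))
  km <- build_kymograph(track, sc$stack, width_px = 20)
  prof <- extract_wide_line_profile(sc$stack$data[1, 1, , ], ax, 20)
  expect_equal(km$membrane[seq_along(prof), 1], prof)
  expect_true(all(attr(km$membrane, "absent")[-1]))
  expect_true(all(km$membrane[, -1] == 0))
})
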