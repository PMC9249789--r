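test_that("max projection takes the per-pixel maximum over Z", {
  # single pixel with Z values (1, 5, 3)
  d <- array(0, c(1, 3, 2, 1, 1))
  d[1, , 1, 1, 1] <- c(1, 5, 3)
  st <- structure(list(data = d, axes = "TZCYX", pixel_size_um = 0.065,
                       frame_interval_min = 3, treatment_start_frame = 1),
                  class = "dbmi_stack")
  expect_equal(max_project(st)$data[1, 1, 1, 1], 5)

  # random block vs brute-force per-pixel maximum
  set.seed(1)
  d <- array(runif(2 * 4 * 2 * 3 * 3), c(2, 4, 2, 3, 3))
  st$data <- d
  proj <- max_project(st)
  for (t in 1:2) for (ch in 1:2) for (y in 1:3) for (x in 1:3) {
    expect_equal(proj$data[t, ch, y, x], max(d[t, , ch, y, x]))
  }

  # single-slice Z equals the input
  st$data <- d[, 1, , , , drop = FALSE]
  expect_equal(max_project(st)$data[, , , ], d[, 1, , , ])

  # no Z axis: identity with a warning
  expect_warning(same <- max_project(proj), "no Z axis")
  expect_identical(same$data, proj$data)
})

test_that("well-separated cells are each recovered by exactly one mask", {
  cfg <- noiseless_config()
  trajs <- simulate_population("dmso_control", 3, cfg, seed = 8)
  rend <- render_timelapse(trajs, cfg)
  lab <- segment_frame(rend$stack$data[1, 1, , ])
  expect_equal(max(lab), 3)
  # masks are disjoint by construction of the labelling; their union fits
  areas <- tabulate(lab[lab > 0])
  expect_true(sum(areas) < prod(dim(lab)))
})

test_that("a blank frame yields no masks", {
  expect_equal(max(segment_frame(matrix(100, 60, 60))), 0)
  noise <- matrix(100 + rnorm(3600, 0, 3), 60, 60)
  expect_equal(max(segment_frame(noise)), 0)
})

test_that("mask area matches the analytic capsule area within 15%", {
  sc <- single_cell_scene(length_um = 3.0)
  lab <- segment_frame(sc$stack$data[1, 1, , ])
  w <- 2 * 0.42 / 0.065                       # cell width in px
  L <- 3.0 / 0.065
  analytic <- (L - w) * w + pi * (w / 2)^2
  expect_lt(abs(sum(lab == 1) - analytic) / analytic, 0.15)
})

test_that("tracking keeps identity under small displacement and never resurrects a track", {
  blank <- matrix(0L, 30, 30)
  sq <- function(r, c) {
    m <- blank
    m[r:(r + 5), c:(c + 5)] <- 1L
    m
  }
  # displaced by 1 px -> same id; vanishes at frame 3 -> absent afterwards
  labs <- list(sq(5, 5), sq(5, 6), blank, blank)
  trks <- track_cells(labs)
  expect_length(trks$tracks, 1)
  expect_equal(trks$tracks[[1]]$present, c(TRUE, TRUE, FALSE, FALSE))

  # reappearing object opens a new id instead of resurrecting the old track
  labs <- list(sq(5, 5), blank, sq(5, 5))
  trks <- track_cells(labs)
  expect_length(trks$tracks, 2)
  expect_equal(trks$tracks[[1]]$present, c(TRUE, FALSE, FALSE))
  expect_equal(trks$tracks[[2]]$present, c(FALSE, FALSE, TRUE))

  # two non-overlapping new objects -> two new ids
  two <- blank; two[2:7, 2:7] <- 1L; two[20:25, 20:25] <- 2L
  trks <- track_cells(list(blank, two))
  expect_length(trks$tracks, 2)
})

test_that("the medial axis of a horizontal capsule recovers its length and orientation", {
  mask <- matrix(FALSE, 30, 60)
  for (x in 1:46) for (y in 1:10) {
    cx <- pmax(0, pmax(6 - x, x - 41))        # capsule: rect + round caps
    if (sqrt(cx^2 + (y - 5.5)^2) <= 5) mask[y + 10, x + 5] <- TRUE
  }
  ax <- medial_axis_of(mask)
  expect_false(ax$degenerate)
  # pole-to-pole arc length matches the mask's occupied column extent
  extent <- diff(range(which(colSums(mask) > 0)))
  expect_true(abs(ax$length_px - extent) <= 2)
  expect_true(abs(ax$length_px - 46) <= 3.5)    # nominal 46-px capsule
  # orientation stability: with a previous frame the pole order is preserved
  prev <- ax$polyline
  ax2 <- medial_axis_of(mask, prev = prev[nrow(prev):1, ])
  expect_lt(sum((ax2$polyline[1, ] - prev[nrow(prev), ])^2), 4)
})

test_that("a disk mask is flagged degenerate with length near its diameter", {
  mask <- matrix(FALSE, 40, 40)
  for (x in 1:40) for (y in 1:40) {
    if ((x - 20)^2 + (y - 20)^2 <= 100) mask[y, x] <- TRUE
  }
  ax <- medial_axis_of(mask)
  expect_true(ax$degenerate)
  expect_lt(abs(ax$length_px - 20), 4)
})

test_that("on noiseless frames every simulated cell is recalled with no spurious detections", {
  run <- noiseless_run("dmso_control")
  lab0 <- segment_frame(run$analysis$tracks$tracks[[1]]$masks[[1]] * 0 + 0)  # trivial blank
  expect_equal(max(lab0), 0)
  expect_equal(length(run$analysis$cell_ids), 5)
  # track count at frame 1 equals the number of units placed
  present0 <- vapply(run$analysis$tracks$tracks, function(tr) tr$present[1],
                     logical(1))
  expect_equal(sum(present0), 5)
})
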