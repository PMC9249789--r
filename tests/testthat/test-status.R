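test_that("status assignment follows the three cell-type definitions", {
  expect_equal(classify_status(0.95, TRUE), "intact")
  expect_equal(classify_status(0.95, FALSE), "no_nucleoid")
  expect_equal(classify_status(0.4, FALSE), "disintegrated")
  expect_equal(classify_status(0.4, TRUE), "disintegrated")
  # enforcing the transition order removes reversals only
  expect_equal(enforce_status_order(c("intact", "no_nucleoid", "intact",
                                      "disintegrated", "no_nucleoid")),
               c("intact", "no_nucleoid", "no_nucleoid", "disintegrated",
                 "disintegrated"))
})

test_that("population status fractions sum to 100 and use the initial cell count", {
  df <- data.frame(cell_id = rep(1:10, 2), frame = rep(1:2, each = 10),
                   status = c(rep("intact", 10),
                              rep(c("intact", "no_nucleoid", "disintegrated"),
                                  c(6, 3, 1))))
  fr <- population_status_fractions(df)
  expect_equal(fr$pct_intact, c(100, 60))
  expect_equal(fr$pct_no_nucleoid, c(0, 30))
  expect_equal(fr$pct_disintegrated, c(0, 10))
  expect_true(all(rowSums(fr[, -1]) == 100))
  expect_error(population_status_fractions(df[0, ]), "no tracked cells")
})

test_that("a control movie stays 100% intact throughout", {
  run <- full_run("dmso_control")
  fr <- run$analysis$status_fractions
  expect_true(all(fr$pct_intact == 100))
  expect_true(all(rowSums(fr[, -1]) == 100))
})

test_that("growth arrest detection matches the simulated onsets", {
  times <- seq(-6, 60, 3)
  # control-like exponential growth: no arrest
  rl <- 100 * 2^((times + 6) / 30)
  expect_true(is.na(detect_growth_arrest(rl, times)$time_min))
  # abrupt arrest at 6 min
  rl6 <- pmin(rl, 100 * 2^(12 / 30))
  expect_equal(detect_growth_arrest(rl6, times)$time_min, 6)
  # degenerate baseline
  flat <- rep(100, length(times))
  res <- detect_growth_arrest(flat, times)
  expect_true(res$degenerate)
  expect_equal(res$time_min, 0)
})

test_that("nucleoid loss detection separates sudden from gradual declines", {
  times <- seq(-6, 60, 3)
  sudden <- ifelse(times >= 6, 3, 100)
  res <- detect_nucleoid_loss(sudden, times)
  expect_equal(res$time_min, 6)
  expect_equal(res$mode, "sudden")
  gradual <- pmax(100 - pmax(times, 0) * 1.6, 20)
  res <- detect_nucleoid_loss(gradual, times)
  expect_equal(res$mode, "gradual")
  expect_equal(res$time_min, times[which(gradual < 50)[1]])
  flat <- rep(100, length(times)) + sin(seq_along(times))
  res <- detect_nucleoid_loss(flat, times)
  expect_true(is.na(res$time_min))
  expect_equal(res$mode, "none")
})

test_that("disintegration detection requires a sustained coverage drop", {
  times <- seq(-6, 60, 3)
  expect_true(is.na(detect_disintegration(rep(1, length(times)), times)))
  cov <- ifelse(times >= 30, 0.35, 1)
  expect_equal(detect_disintegration(cov, times), 30)
  dip <- rep(1, length(times)); dip[10] <- 0.3   # single-frame dip: ignored
  expect_true(is.na(detect_disintegration(dip, times)))
})

test_that("noiseless event times are recovered within one frame for every preset", {
  for (nm in list_presets()) {
    run <- noiseless_run(nm)
    truth <- trajectory_events(run$trajectories)
    for (e in run$analysis$events) {
      tr <- truth[truth$cell_id == e$cell_id, ]
      if (nrow(tr) == 0) next
      if (!is.na(tr$nucleoid_loss_min) ) {
        expect_lte(abs(e$nucleoid_loss_min - tr$nucleoid_loss_min), 3,
                   label = sprintf("%s loss (cell %d)", nm, e$cell_id))
        expect_equal(e$nucleoid_loss_mode, "sudden",
                     label = sprintf("%s loss mode", nm))
      }
      if (tr$arrest_mode %in% c("abrupt", "shrink") && !is.na(tr$arrest_min)) {
        expect_lte(abs(e$growth_arrest_min - tr$arrest_min), 3,
                   label = sprintf("%s arrest (cell %d)", nm, e$cell_id))
      }
      if (!is.na(tr$disintegration_min)) {
        expect_lte(abs(e$disintegration_min - tr$disintegration_min), 3,
                   label = sprintf("%s disintegration (cell %d)", nm, e$cell_id))
      } else {
        expect_true(is.na(e$disintegration_min),
                    info = sprintf("%s spurious disintegration", nm))
      }
    }
  }
})

test_that("membrane features are detected for the presets that induce them", {
  blobs <- function(run) vapply(run$analysis$events, function(e) e$blobs,
                                character(1))
  expect_true(mean(blobs(full_run("nisin")) == "large_blobs") > 0.5)
  expect_true(mean(blobs(full_run("triclosan")) == "small_foci") > 0.5)
  expect_true(all(blobs(full_run("cccp")) == "none"))
  # nisin blobs appear only after the loss event
  for (e in full_run("nisin")$analysis$events) {
    if (e$blobs == "large_blobs") expect_gte(e$blob_onset_min, e$nucleoid_loss_min)
  }
})

test_that("nucleoid elongation state separates protein, DNA and control responses", {
  states <- function(run) vapply(run$analysis$events,
                                 function(e) e$nucleoid_elongation_state,
                                 character(1))
  expect_true(mean(states(noiseless_run("chloramphenicol")) == "arrested") > 0.5)
  expect_true(mean(states(noiseless_run("moxifloxacin")) == "slowed") > 0.5)
  expect_true(all(states(noiseless_run("dmso_control")) == "normal"))
})

test_that("the ratio trend captures decondensation and compaction", {
  trend <- function(run) vapply(run$analysis$events, function(e) e$ratio_trend,
                                character(1))
  rif <- noiseless_run("rifampin")
  expect_true(all(trend(rif) == "increasing"))
  expect_true(all(vapply(rif$analysis$events,
                         function(e) e$decondensation_extent, numeric(1)) >= 0.9))
  expect_true(mean(trend(noiseless_run("chloramphenicol")) == "decreasing") > 0.5)
  expect_true(all(trend(noiseless_run("dmso_control")) == "stable"))
})

test_that("sudden-mode detections imply a >40-point frame-to-frame drop", {
  for (nm in c("cccp", "ampicillin", "nisin")) {
    run <- full_run(nm)
    f <- run$analysis$features
    for (e in run$analysis$events) {
      if (e$nucleoid_loss_mode != "sudden") next
      ri <- f$rel_intensity_pct[f$cell_id == e$cell_id]
      expect_gt(max(-diff(ri), na.rm = TRUE), 40,
                label = sprintf("%s cell %d", nm, e$cell_id))
    }
  }
})
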