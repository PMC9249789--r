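test_that("single-cell classification follows the decision scheme", {
  # simultaneous sudden loss and arrest -> membrane
  m <- classify_cell(make_events(arrest = 6, loss = 6, mode = "sudden"))
  expect_equal(m$level1, "envelope")
  expect_equal(m$level2, "membrane")

  # arrest two frames before sudden loss plus disintegration -> wall
  w <- classify_cell(make_events(arrest = 18, loss = 24, mode = "sudden",
                                 disint = 33))
  expect_equal(w$level2, "wall")

  # sudden loss with neither signature -> unclassified with explanatory evidence
  u <- classify_cell(make_events(loss = 24, mode = "sudden"))
  expect_equal(u$level2, "unclassified")
  expect_true(any(grepl("conflict", u$evidence$criterion)))

  # increasing ratio -> rna
  r <- classify_cell(make_events(trend = "increasing", extent = 0.95))
  expect_equal(r$level2, "rna")
  expect_equal(r$level1, "non_envelope")

  # decreasing ratio with arrested / slowed nucleoid elongation
  p <- classify_cell(make_events(trend = "decreasing", elong = "arrested"))
  expect_equal(p$level2, "protein")
  d <- classify_cell(make_events(trend = "decreasing", elong = "slowed"))
  expect_equal(d$level2, "dna")

  # no events at all -> control
  c0 <- classify_cell(make_events())
  expect_equal(c0$level2, "control")
  expect_equal(c0$level1, "control")
})

test_that("level-2 classes imply the correct envelope grouping", {
  for (evts in list(make_events(arrest = 6, loss = 6, mode = "sudden"),
                    make_events(arrest = 18, loss = 24, mode = "sudden",
                                disint = 33),
                    make_events(trend = "increasing", extent = 0.95),
                    make_events(trend = "decreasing", elong = "arrested"),
                    make_events(trend = "decreasing", elong = "slowed"))) {
    cc <- classify_cell(evts)
    if (cc$level2 %in% c("membrane", "wall")) {
      expect_equal(cc$level1, "envelope")
    } else if (cc$level2 %in% c("protein", "dna", "rna")) {
      expect_equal(cc$level1, "non_envelope")
    }
    expect_gt(nrow(cc$evidence), 0)
  }
})

test_that("sub-classification resolves membrane, wall and rna but never protein/dna", {
  nis <- subclassify("membrane",
                     make_events(arrest = 6, loss = 6, mode = "sudden",
                                 shrinkage = TRUE, blobs = "large_blobs",
                                 blob_onset = 30))
  expect_equal(nis$level3, "pore_former")
  dep <- subclassify("membrane", make_events(arrest = 6, loss = 6,
                                             mode = "sudden"))
  expect_equal(dep$level3, "depolarizer")

  van <- subclassify("wall",
                     make_events(arrest = 42, loss = 51, mode = "sudden",
                                 disint = 57, blobs = "large_blobs",
                                 blob_onset = 24))
  expect_equal(van$level3, "lipid_II_inhibitor")
  amp <- subclassify("wall", make_events(arrest = 18, loss = 27,
                                         mode = "sudden", disint = 33))
  expect_equal(amp$level3, "transpeptidation_inhibitor")

  rif <- subclassify("rna", make_events(trend = "increasing", extent = 0.96))
  expect_equal(rif$level3, "rnap_inhibitor")
  act <- subclassify("rna", make_events(trend = "increasing", extent = 0.68))
  expect_equal(act$level3, "transcription_complex_inhibitor")

  pr <- subclassify("protein", make_events(trend = "decreasing",
                                           elong = "arrested"))
  expect_equal(pr$level3, "none")
  expect_true(grepl("sub-classes", pr$evidence$threshold))
})

test_that("population calls use majority vote with the wall disintegration safeguard", {
  mem <- make_events(arrest = 6, loss = 6, mode = "sudden")
  wall <- make_events(arrest = 18, loss = 24, mode = "sudden", disint = 33)
  ctrl <- make_events()

  calls <- lapply(rep(list(ctrl), 9), classify_cell)
  pop <- classify_compound(calls, rep(list(ctrl), 9))
  expect_equal(pop$level2, "control")

  # tie between two classes -> unclassified
  evs <- c(rep(list(mem), 4), rep(list(wall), 4), list(ctrl))
  pop <- classify_compound(lapply(evs, classify_cell), evs)
  expect_equal(pop$level2, "unclassified")

  # wall majority without enough observed disintegration is rejected
  wall_nodis <- make_events(arrest = 18, loss = 24, mode = "sudden",
                            disint = 33)
  calls <- lapply(rep(list(wall_nodis), 9), classify_cell)
  evs_nodis <- rep(list(make_events(arrest = 18, loss = 24, mode = "sudden")), 9)
  pop <- classify_compound(calls, evs_nodis)
  expect_equal(pop$level2, "unclassified")

  # too few cells is an error stating the requirement
  expect_error(classify_compound(lapply(rep(list(mem), 3), classify_cell)),
               "at least 5")
})

test_that("vote fractions sum to one and the call is order-invariant", {
  mem <- make_events(arrest = 6, loss = 6, mode = "sudden")
  wall <- make_events(arrest = 18, loss = 24, mode = "sudden", disint = 33)
  evs <- c(rep(list(mem), 6), rep(list(wall), 3))
  calls <- lapply(evs, classify_cell)
  pop <- classify_compound(calls, evs)
  expect_equal(sum(pop$vote_fractions), 1)
  set.seed(4)
  for (k in 1:5) {
    perm <- sample(length(calls))
    pop2 <- classify_compound(calls[perm], evs[perm])
    expect_equal(pop2$level2, pop$level2)
    expect_equal(pop2$level3, pop$level3)
  }
})

test_that("the evidence trail alone reproduces the decisive verdicts", {
  w <- classify_cell(make_events(arrest = 18, loss = 24, mode = "sudden",
                                 disint = 33))
  ev <- w$evidence
  expect_true(all(c("nucleoid_loss_mode", "arrest_loss_interval",
                    "arrest_before_loss", "disintegration_observed") %in%
                    ev$criterion))
  # re-apply the recorded thresholds to the recorded observations
  dt <- as.numeric(ev$observed[ev$criterion == "arrest_loss_interval"])
  expect_false(abs(dt) <= 3)                       # not simultaneous
  expect_true(dt <= -6)                            # arrest >= 2 frames first
  expect_equal(ev$verdict[ev$criterion == "disintegration_observed"], "yes")
})
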