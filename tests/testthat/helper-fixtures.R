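# Shared fixtures: simulated/analysed runs are cached so the expensive
# end-to-end pipelines are executed once per preset per test session.

.fixtures <- new.env(parent = emptyenv())

# Default-noise end-to-end run (9 cells), one fixed seed per preset.
full_run <- function(preset, n_cells = 9) {
  key <- sprintf("full_%s_%d", preset, n_cells)
  if (is.null(.fixtures[[key]])) {
    seed <- 100 + match(preset, list_presets())
    .fixtures[[key]] <- run_pipeline(preset, n_cells = n_cells, seed = seed)
  }
  .fixtures[[key]]
}

# Noiseless run used by the calibration / event-recovery oracles.
noiseless_run <- function(preset, n_cells = 5) {
  key <- sprintf("clean_%s_%d", preset, n_cells)
  if (is.null(.fixtures[[key]])) {
    seed <- 40 + match(preset, list_presets())
    .fixtures[[key]] <- run_pipeline(preset, n_cells = n_cells, seed = seed,
                                     noiseless = TRUE)
  }
  .fixtures[[key]]
}

noiseless_config <- function(...) {
  scene_config(poisson_scale = 0, gaussian_read_noise = 0, ...)
}

# A single noiseless rendered cell of fixed length with one fixed nucleoid
# segment pair; returns stack + geometry.
single_cell_scene <- function(length_um = 3.0, segments = cbind(1.0, 2.0),
                              intensity = 1, seed = 3) {
  cfg <- noiseless_config()
  tr <- simulate_population("dmso_control", 1, cfg, seed = seed)
  tr$cells[[1]]$length_um[] <- length_um
  tr$cells[[1]]$nucleoid_segments <- lapply(tr$cells[[1]]$nucleoid_segments,
                                            function(s) segments)
  tr$cells[[1]]$intensity_fraction[] <- intensity
  tr$cells[[1]]$nucleoid_length_um[] <- sum(segments[, 2] - segments[, 1])
  tr$cells[[1]]$divisions <- numeric(0)
  tr$cells[[1]]$septa_frac <- list()
  rend <- render_timelapse(tr, cfg)
  list(stack = rend$stack, truth = rend$truth, config = cfg, trajs = tr)
}

# Event list template for the decision-scheme unit tests.
make_events <- function(arrest = NA_real_, loss = NA_real_, mode = "none",
                        disint = NA_real_, blobs = "none",
                        blob_onset = NA_real_, shrinkage = FALSE,
                        elong = "normal", trend = "stable", extent = 0.55) {
  list(growth_arrest_min = arrest, degenerate_baseline = FALSE,
       nucleoid_loss_min = loss, nucleoid_loss_mode = mode,
       disintegration_min = disint, blobs = blobs,
       blob_onset_min = blob_onset, shrinkage = shrinkage,
       nucleoid_elongation_state = elong, ratio_trend = trend,
       decondensation_extent = extent)
}
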