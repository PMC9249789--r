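# Pipeline entry points: simulate -> analyze -> classify -> report.
# Each writes plain standard formats (TIFF, CSV, JSON, PNG, YAML) so a run
# directory is fully reproducible from its saved config and seed.

.log <- function(fmt, ..., verbose = TRUE) {
  if (verbose) message(format(Sys.time(), "%H:%M:%S "), sprintf(fmt, ...))
}

#' Simulate a compound and write the stack + ground truth
#'
#' @param preset preset name (see [list_presets()]) or a
#'   [drug_response_preset()].
#' @param n_cells number of cell units.
#' @param seed integer seed driving both trajectories and rendering noise.
#' @param out_dir output directory (created if needed).
#' @param config a [scene_config()]; its `rng_seed` is replaced by
#'   `seed + 1` so trajectory sampling and render noise use distinct
#'   streams.
#' @param noiseless disable shot/read noise (used by calibration tests).
#' @return list of written paths (`stack`, `truth`, `config`) plus the
#'   in-memory `trajectories`, `stack` and `truth` table.
#' @export
dbmi_simulate <- function(preset, n_cells = 9, seed = 1L, out_dir = NULL,
                          config = scene_config(), noiseless = FALSE) {
  if (is.character(preset)) preset <- get_preset(preset)
  config$rng_seed <- as.integer(seed) + 1L
  if (noiseless) {
    config$poisson_scale <- 0
    config$gaussian_read_noise <- 0
  }
  trajs <- simulate_population(preset, n_cells, config, seed = seed)
  rend <- render_timelapse(trajs, config)
  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stack_path <- file.path(out_dir, sprintf("%s_stack.tif", preset$name))
    write_stack(rend$stack, stack_path, truth = rend$truth)
    cfg_path <- file.path(out_dir, "scene_config.yaml")
    yaml::write_yaml(c(list(preset = preset$name, n_cells = n_cells,
                            seed = as.integer(seed)),
                       unclass(config)[!vapply(config, is.null, logical(1))]),
                     cfg_path)
    paths <- list(stack = stack_path,
                  truth = sub("\\.[^.]+$", "_truth.csv", stack_path),
                  config = cfg_path)
  }
  c(paths, list(trajectories = trajs, stack = rend$stack, truth = rend$truth))
}

#' Analyse a stack and write the quantification outputs
#'
#' @param stack a `dbmi_stack` or path to a TIFF written by [write_stack()].
#' @param out_dir output directory (NULL = in-memory only).
#' @param opts a [dbmi_options()] list.
#' @param kymographs write per-cell kymograph CSV + PNG heatmaps.
#' @param verbose log progress to stderr.
#' @return the [analyze_stack()] result (with `paths` attached when
#'   `out_dir` is given).
#' @export
dbmi_analyze <- function(stack, out_dir = NULL, opts = dbmi_options(),
                         kymographs = !is.null(out_dir), verbose = FALSE) {
  if (is.character(stack)) stack <- read_stack(stack)
  .log("analysing %d frames", dim(stack$data)[1], verbose = verbose)
  res <- analyze_stack(stack, opts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    if (!is.null(res$status_fractions)) {
      utils::write.csv(res$status_fractions,
                       file.path(out_dir, "status_fractions.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(res$events, file.path(out_dir, "events.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    yaml::write_yaml(unclass(res$opts), file.path(out_dir, "options.yaml"))
    if (kymographs) {
      ks <- analysis_kymographs(res, stack)
      for (cid in names(ks)) {
        for (ch in c("membrane", "nucleoid")) {
          utils::write.csv(ks[[cid]][[ch]],
                           file.path(out_dir, sprintf("kymograph_cell%s_%s.csv",
                                                      cid, ch)),
                           row.names = FALSE)
          kymograph_png(ks[[cid]][[ch]],
                        file.path(out_dir, sprintf("kymograph_cell%s_%s.png",
                                                   cid, ch)),
                        main = sprintf("cell %s (%s)", cid, ch))
        }
      }
    }
    attr(res, "paths") <- list(features = file.path(out_dir, "features.csv"),
                               events = file.path(out_dir, "events.json"))
  }
  res
}

#' Classify a compound from an analysis
#'
#' @param analysis a [analyze_stack()]/[dbmi_analyze()] result, or the path
#'   of an analysis output directory containing `events.json`.
#' @param compound compound label for the report.
#' @param out_dir where to write `call.json` and `report.md` (NULL =
#'   in-memory only).
#' @param opts a [dbmi_options()] list.
#' @return the population [classify_compound()] call.
#' @export
dbmi_classify <- function(analysis, compound = "unknown", out_dir = NULL,
                          opts = dbmi_options()) {
  events <- if (inherits(analysis, "dbmi_analysis")) analysis$events
  else {
    p <- if (dir.exists(analysis)) file.path(analysis, "events.json") else analysis
    if (!file.exists(p)) stop(sprintf("no events found at '%s'", p))
    ej <- jsonlite::read_json(p, simplifyVector = FALSE)
    lapply(ej, function(e) {
      for (k in c("growth_arrest_min", "nucleoid_loss_min",
                  "disintegration_min", "blob_onset_min",
                  "decondensation_extent")) {
        if (is.null(e[[k]])) e[[k]] <- NA_real_ else e[[k]] <- as.numeric(e[[k]])
      }
      e
    })
  }
  fi <- if (inherits(analysis, "dbmi_analysis"))
    analysis$stack_meta$frame_interval_min else 3
  calls <- lapply(events, classify_cell, opts = opts, frame_interval_min = fi)
  pop <- classify_compound(calls, events, opts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(compound = compound, level1 = pop$level1, level2 = pop$level2,
           level3 = pop$level3, n_cells = pop$n_cells,
           votes = as.list(pop$votes), vote_fractions = as.list(pop$vote_fractions),
           evidence = pop$evidence),
      file.path(out_dir, "call.json"), auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(.call_report(pop, compound), file.path(out_dir, "report.md"))
  }
  pop
}

.call_report <- function(pop, compound) {
  lines <- c(sprintf("# Mechanism-of-action call: %s", compound), "",
             sprintf("* Level 1 (envelope association): **%s**", pop$level1),
             sprintf("* Level 2 (target class): **%s**", pop$level2),
             sprintf("* Level 3 (sub-class): **%s**", pop$level3),
             sprintf("* Cells analysed: %d", pop$n_cells), "",
             "## Population evidence", "")
  ev <- pop$evidence
  for (i in seq_len(nrow(ev))) {
    lines <- c(lines, sprintf("- %s: observed `%s` vs `%s` -> %s",
                              ev$criterion[i], ev$observed[i],
                              ev$threshold[i], ev$verdict[i]))
  }
  lines <- c(lines, "", "## Per-cell votes", "")
  if (!is.null(pop$votes)) {
    for (nm in names(pop$votes)) {
      if (pop$votes[[nm]] > 0) {
        lines <- c(lines, sprintf("- %s: %d", nm, pop$votes[[nm]]))
      }
    }
  }
  lines
}

#' Run the full pipeline for one compound in memory
#'
#' simulate -> render -> analyse -> classify, no files written.
#'
#' @param preset preset name.
#' @param n_cells cells to simulate.
#' @param seed integer seed.
#' @param config a [scene_config()].
#' @param opts a [dbmi_options()] list.
#' @param noiseless disable rendering noise.
#' @return list with `trajectories`, `truth`, `analysis`, `call`.
#' @export
run_pipeline <- function(preset, n_cells = 9, seed = 1L,
                         config = scene_config(), opts = dbmi_options(),
                         noiseless = FALSE) {
  sim <- dbmi_simulate(preset, n_cells = n_cells, seed = seed,
                       config = config, noiseless = noiseless)
  ana <- analyze_stack(sim$stack, opts)
  call <- dbmi_classify(ana, compound = sim$trajectories$preset$name,
                        opts = opts)
  list(trajectories = sim$trajectories, truth = sim$truth, analysis = ana,
       call = call)
}

#' Multi-compound summary report
#'
#' @param calls named list of [dbmi_classify()] results (name = compound).
#' @param analyses optional named list of matching analyses for the
#'   status-fraction and relative-series plots.
#' @param out_dir output directory.
#' @return the summary data frame (written as `summary.csv`).
#' @export
dbmi_report <- function(calls, analyses = NULL, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- do.call(rbind, lapply(names(calls), function(nm) {
    cc <- calls[[nm]]
    data.frame(compound = nm, level1 = cc$level1, level2 = cc$level2,
               level3 = cc$level3, n_cells = cc$n_cells)
  }))
  utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(analyses)) {
    for (nm in names(analyses)) {
      an <- analyses[[nm]]
      if (is.null(an$features)) next
      grDevices::png(file.path(out_dir, sprintf("%s_series.png", nm)),
                     width = 1200, height = 400)
      graphics::par(mfrow = c(1, 3))
      .series_panel(an, "rel_length_pct", "relative cell length (%)", nm)
      .series_panel(an, "rel_intensity_pct", "relative nucleoid intensity (%)", nm)
      sf <- an$status_fractions
      graphics::matplot(an$times[sf$frame], sf[, -1], type = "l", lty = 1,
                        col = c("darkgreen", "orange", "red"),
                        xlab = "time (min)", ylab = "cells (%)",
                        main = sprintf("%s: cell status", nm))
      graphics::legend("right", c("intact", "no nucleoid", "disintegrated"),
                       col = c("darkgreen", "orange", "red"), lty = 1, cex = 0.8)
      grDevices::dev.off()
    }
  }
  summary
}

.series_panel <- function(an, col, ylab, nm) {
  f <- an$features
  wide <- tapply(f[[col]], list(f$frame, f$cell_id), mean)
  graphics::matplot(an$times[as.integer(rownames(wide))], wide, type = "l",
                    lty = 1, col = "grey60", xlab = "time (min)", ylab = ylab,
                    main = nm)
  graphics::lines(an$times[as.integer(rownames(wide))],
                  rowMeans(wide, na.rm = TRUE), lwd = 2)
}
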