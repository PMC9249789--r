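#' Analysis options (all tunable thresholds in one place)
#'
#' Every surrogate threshold used by the pipeline, with its default and the
#' stage that consumes it. Unknown keys are rejected.
#'
#' \describe{
#'   \item{width_px (20)}{wide-line profile width; 20 px = 1.3 um at 0.065
#'     um/px (profiling).}
#'   \item{k_sigma (3)}{nucleoid/membrane detectability threshold above
#'     background, in background SDs (profiling, status).}
#'   \item{rel_floor (0.5)}{nucleoid segment edge at this fraction of the
#'     in-cell peak: half-maximum edge criterion (profiling).}
#'   \item{smooth_sigma_px, close_radius_px, min_area_px}{segmentation
#'     recipe (imaging).}
#'   \item{arrest_rate_frac (0.1), arrest_consecutive (2)}{growth-arrest
#'     detector (status_events).}
#'   \item{loss_threshold_pct (50), sudden_high_pct (60), sudden_low_pct
#'     (20), sudden_max_frames (2), gradual_min_frames (4)}{nucleoid-loss
#'     detector (status_events).}
#'   \item{disintegration_coverage (0.6)}{membrane-integrity cut-off
#'     (status_events).}
#'   \item{feature_intensity_factor (1.5), a_blob_px (20)}{membrane feature
#'     detector; a_blob_px separates small foci from large blobs
#'     (status_events).}
#'   \item{smoothing}{all series pass a fixed 3-frame moving median before
#'     event detection.}
#'   \item{simultaneity_frames (1), before_frames (2)}{frame windows
#'     operationalising "simultaneous" and "before" at the acquisition
#'     resolution (moa).}
#'   \item{shrinkage_pct (5)}{relative-length drop from the running maximum
#'     scoring cell shrinkage (moa level 3).}
#'   \item{elong_arrest_frac (0.1), elong_slow_frac (0.7)}{nucleoid
#'     elongation state cut-offs vs the control-calibrated slope
#'     (status_events).}
#'   \item{ratio_deadband_frac (0.1)}{ratio-trend dead-band per 60 min
#'     (status_events).}
#'   \item{decondensation_cutoff (0.9)}{complete vs partial decondensation
#'     (moa level 3).}
#'   \item{wall_disintegration_frac (0.2), min_cells (5)}{population call
#'     rules (moa).}
#'   \item{doubling_time_min (30)}{untreated doubling time calibrating the
#'     reference nucleoid-elongation slope.}
#'   \item{exclude_border (TRUE)}{censor cells touching the image border.}
#' }
#'
#' @param ... overrides of the defaults above.
#' @return named list of class `dbmi_options`.
#' @export
dbmi_options <- function(...) {
  defaults <- list(
    width_px = 20, k_sigma = 3, rel_floor = 0.5,
    smooth_sigma_px = 1, close_radius_px = 2, min_area_px = 100,
    arrest_rate_frac = 0.1, arrest_consecutive = 2,
    loss_threshold_pct = 50, sudden_high_pct = 60, sudden_low_pct = 20,
    sudden_max_frames = 2, gradual_min_frames = 4,
    disintegration_coverage = 0.6,
    feature_intensity_factor = 1.5, a_blob_px = 20,
    simultaneity_frames = 1, before_frames = 2,
    shrinkage_pct = 5,
    elong_arrest_frac = 0.1, elong_slow_frac = 0.7,
    ratio_deadband_frac = 0.1,
    decondensation_cutoff = 0.9,
    wall_disintegration_frac = 0.2, min_cells = 5,
    doubling_time_min = 30,
    exclude_border = TRUE
  )
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) {
    stop(sprintf("unknown option key(s): %s", paste(bad, collapse = ", ")))
  }
  defaults[names(over)] <- over
  structure(defaults, class = c("dbmi_options", "list"))
}
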