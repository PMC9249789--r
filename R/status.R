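# Per-frame cell status, population fractions, and timed event detection.
#
# All series are smoothed with a 3-frame moving median before event
# detection; detected times lie on the acquisition frame grid.

.smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  out <- x
  for (i in 2:(n - 1)) {
    w <- x[(i - 1):(i + 1)]
    if (all(is.na(w))) next
    out[i] <- stats::median(w, na.rm = TRUE)
  }
  out
}

#' Classify per-frame cell status
#'
#' Three types: intact (membrane intact, nucleoid detectable), no_nucleoid
#' (membrane intact, nucleoid undetectable), disintegrated (membrane
#' integrity lost).
#'
#' @param membrane_coverage fraction (0-1) of the cell's axial extent with a
#'   detectable membrane signal; below `coverage_cutoff` the envelope is
#'   scored as disintegrated.
#' @param nucleoid_detectable logical.
#' @param coverage_cutoff integrity cut-off (default 0.6).
#' @return character vector of statuses.
#' @export
classify_status <- function(membrane_coverage, nucleoid_detectable,
                            coverage_cutoff = 0.6) {
  ifelse(membrane_coverage < coverage_cutoff, "disintegrated",
         ifelse(nucleoid_detectable, "intact", "no_nucleoid"))
}

#' Enforce the monotone status order intact -> no_nucleoid -> disintegrated
#'
#' @param status character vector over frames.
#' @return status vector with reversals removed (a cell never becomes intact
#'   again after losing its nucleoid, nor un-disintegrates).
#' @export
enforce_status_order <- function(status) {
  lev <- c(intact = 1L, no_nucleoid = 2L, disintegrated = 3L)
  num <- cummax(lev[status])
  names(lev)[num]
}

#' Population cell-status fractions per frame
#'
#' @param status_df data frame with columns `cell_id`, `frame`, `status`.
#'   Cell units absent from a frame must already carry status
#'   "disintegrated".
#' @return data frame (frame, pct_intact, pct_no_nucleoid,
#'   pct_disintegrated); the three columns sum to exactly 100 at every frame.
#'   The denominator is the number of cell units defined at the initial
#'   frame.
#' @export
population_status_fractions <- function(status_df) {
  if (!nrow(status_df)) stop("no tracked cells: cannot compute status fractions")
  n0 <- length(unique(status_df$cell_id))
  frames <- sort(unique(status_df$frame))
  out <- do.call(rbind, lapply(frames, function(f) {
    st <- status_df$status[status_df$frame == f]
    counts <- c(intact = sum(st == "intact"),
                no_nucleoid = sum(st == "no_nucleoid"),
                disintegrated = sum(st == "disintegrated"))
    data.frame(frame = f,
               pct_intact = 100 * counts[["intact"]] / n0,
               pct_no_nucleoid = 100 * counts[["no_nucleoid"]] / n0,
               pct_disintegrated = 100 * counts[["disintegrated"]] / n0)
  }))
  rownames(out) <- NULL
  out
}

#' Detect growth arrest from a relative-cell-length series
#'
#' The pre-treatment frames calibrate the baseline per-minute relative
#' growth rate; arrest is the start of the first post-treatment interval
#' whose smoothed rate falls below `rate_frac` of baseline for at least
#' `consecutive` intervals.
#'
#' @param rel_length relative cell length (% of t = 0), one value per frame.
#' @param times frame times in min (treatment at 0; >= 2 pre-treatment
#'   frames required).
#' @param rate_frac arrest threshold as a fraction of the baseline rate.
#' @param consecutive required consecutive sub-threshold intervals.
#' @return list with `time_min` (NA if growth never arrests) and
#'   `degenerate` (TRUE when the baseline rate was not positive, in which
#'   case `time_min` is 0).
#' @export
detect_growth_arrest <- function(rel_length, times, rate_frac = 0.1,
                                 consecutive = 2) {
  stopifnot(length(rel_length) == length(times), sum(times < 0) >= 2)
  s <- .smooth3(rel_length)
  n <- length(s)
  dt <- diff(times)
  rate <- diff(s) / s[-n] / dt          # per-minute relative rate, interval i = [t_i, t_i+1]
  pre <- which(times[-1] <= 0)
  baseline <- mean(rate[pre], na.rm = TRUE)
  if (!is.finite(baseline) || baseline <= 0) {
    return(list(time_min = 0, degenerate = TRUE))
  }
  thr <- rate_frac * baseline
  low <- rate < thr & times[-n] >= 0
  low[is.na(low)] <- FALSE
  run <- 0
  for (i in seq_along(low)) {
    run <- if (low[i]) run + 1 else 0
    if (run >= consecutive) {
      return(list(time_min = times[i - consecutive + 1], degenerate = FALSE))
    }
  }
  list(time_min = NA_real_, degenerate = FALSE)
}

#' Detect loss of nucleoid fluorescence and its mode
#'
#' Loss time is the first post-treatment frame below `loss_pct` of the t = 0
#' intensity. The mode is sudden when the series falls from >= `high_pct` to
#' <= `low_pct` within at most `sudden_frames` frames, gradual when the 50%
#' crossing is reached by a decline spanning at least `gradual_frames`
#' frames, and none otherwise.
#'
#' @param rel_intensity relative nucleoid intensity (% of t = 0) per frame.
#' @param times frame times (min).
#' @param loss_pct,high_pct,low_pct,sudden_frames,gradual_frames thresholds.
#' @return list with `time_min` (NA if never lost) and `mode` (sudden,
#'   gradual, none).
#' @export
detect_nucleoid_loss <- function(rel_intensity, times, loss_pct = 50,
                                 high_pct = 60, low_pct = 20,
                                 sudden_frames = 2, gradual_frames = 4) {
  s <- .smooth3(rel_intensity)
  post <- which(times >= 0 & s < loss_pct)
  if (!length(post)) return(list(time_min = NA_real_, mode = "none"))
  f <- post[1]
  mode <- "none"
  n <- length(s)
  for (i in seq_len(n - 1)) {
    jmax <- min(n, i + sudden_frames)
    if (s[i] >= high_pct && any(s[(i + 1):jmax] <= low_pct, na.rm = TRUE)) {
      mode <- "sudden"
      break
    }
  }
  if (mode == "none") {
    hi <- which(seq_len(n) < f & s >= 80)
    if (length(hi) && (f - max(hi)) >= gradual_frames) mode <- "gradual"
  }
  list(time_min = times[f], mode = mode)
}

#' Detect envelope disintegration from a membrane-coverage series
#'
#' @param coverage membrane coverage per frame (0-1; 0 for frames where the
#'   cell is no longer detectable).
#' @param times frame times (min).
#' @param cutoff coverage below this, sustained to the end of the movie,
#'   scores disintegration.
#' @return disintegration time in min, or NA.
#' @export
detect_disintegration <- function(coverage, times, cutoff = 0.6) {
  s <- .smooth3(coverage)
  n <- length(s)
  below <- s < cutoff
  below[is.na(below)] <- FALSE
  cand <- which(below & times >= 0)
  for (f in cand) {
    if (all(below[f:n])) return(times[f])
  }
  NA_real_
}

#' Detect bright membrane features (foci / blobs) in one frame
#'
#' Connected regions of membrane signal exceeding `factor` times the cell's
#' reference membrane intensity (the median peak signal along the axis) are
#' features; their pixel area separates small foci from large blobs.
#'
#' @param img membrane-channel frame.
#' @param mask logical cell mask.
#' @param axis medial axis of the cell ([medial_axis_of()] result).
#' @param factor intensity multiple of the reference defining a feature.
#' @param a_blob_px area cut-off between small_foci and large_blobs.
#' @param width_px profile width for the reference intensity.
#' @return list with `type` (none / small_foci / large_blobs) and `areas`
#'   (px of each detected feature).
#' @export
detect_membrane_features <- function(img, mask, axis, factor = 1.5,
                                     a_blob_px = 20, width_px = 20) {
  peaks <- extract_wide_line_profile(img, axis, width_px, agg = "max")
  ref <- stats::median(peaks)
  if (!is.finite(ref) || ref <= 0) return(list(type = "none", areas = integer(0)))
  bw <- mask & img > factor * ref
  if (!any(bw)) return(list(type = "none", areas = integer(0)))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
  areas <- tabulate(lab[lab > 0])
  areas <- areas[areas > 2]               # ignore isolated noise pixels
  if (!length(areas)) return(list(type = "none", areas = integer(0)))
  list(type = if (any(areas >= a_blob_px)) "large_blobs" else "small_foci",
       areas = areas)
}

#' Nucleoid elongation state relative to untreated growth
#'
#' Least-squares slope of the relative nucleoid length over the
#' post-treatment window before any loss event, compared with the
#' control-calibrated slope `100 * log(2) / doubling_time` (%/min).
#'
#' @param rel_nucleoid_length relative nucleoid length (% of t = 0).
#' @param times frame times (min).
#' @param window_end_min end of the usable window (the loss time, or Inf).
#' @param doubling_time_min untreated doubling time calibrating the
#'   reference slope.
#' @param arrest_frac,slow_frac state cut-offs as fractions of the reference
#'   slope.
#' @return one of "arrested", "slowed", "normal", or "undetermined" (window
#'   shorter than 4 frames).
#' @export
nucleoid_elongation_state <- function(rel_nucleoid_length, times,
                                      window_end_min = Inf,
                                      doubling_time_min = 30,
                                      arrest_frac = 0.1, slow_frac = 0.7) {
  keep <- times >= 0 & times < window_end_min & is.finite(rel_nucleoid_length)
  if (sum(keep) < 4) return("undetermined")
  y <- .smooth3(rel_nucleoid_length[keep])
  x <- times[keep]
  slope <- stats::cov(x, y) / stats::var(x)
  ref <- 100 * log(2) / doubling_time_min
  frac <- slope / ref
  if (frac <= arrest_frac) "arrested" else if (frac < slow_frac) "slowed" else "normal"
}

#' Trend of the nucleoid/cell length ratio before loss
#'
#' @param ratio ratio series (0-1, NA allowed).
#' @param times frame times (min).
#' @param window_end_min end of the usable window (loss time, or Inf).
#' @param deadband_frac slope dead-band: +-`deadband_frac` of the initial
#'   ratio per 60 min counts as stable.
#' @return list with `trend` (increasing / decreasing / stable) and
#'   `extent` (maximum smoothed ratio reached, the decondensation extent).
#' @export
ratio_trend <- function(ratio, times, window_end_min = Inf,
                        deadband_frac = 0.1) {
  keep <- times >= 0 & times < window_end_min & is.finite(ratio)
  sm_all <- .smooth3(ratio)
  extent <- if (any(keep)) max(sm_all[keep], na.rm = TRUE) else NA_real_
  if (sum(keep) < 4) return(list(trend = "stable", extent = extent))
  y <- .smooth3(ratio[keep])
  x <- times[keep]
  slope <- stats::cov(x, y) / stats::var(x)
  r0 <- y[1]
  db <- deadband_frac * r0 / 60
  trend <- if (slope > db) "increasing" else if (slope < -db) "decreasing" else "stable"
  list(trend = trend, extent = extent)
}

#' Timed events of one cell from its measured series
#'
#' Aggregates every detector into the event summary consumed by the
#' mechanism-of-action decision scheme.
#'
#' @param series per-frame data frame for one cell with columns `time_min`,
#'   `rel_length_pct`, `rel_intensity_pct`, `rel_nucleoid_pct`, `ratio`,
#'   `coverage`, `feature_type` (per-frame none/small_foci/large_blobs) and
#'   `present`.
#' @param opts a [dbmi_options()] list.
#' @return an event list (`growth_arrest_min`, `nucleoid_loss_min`,
#'   `nucleoid_loss_mode`, `disintegration_min`, `blobs`, `blob_onset_min`,
#'   `shrinkage`, `nucleoid_elongation_state`, `ratio_trend`,
#'   `decondensation_extent`, `degenerate_baseline`).
#' @export
cell_events <- function(series, opts = dbmi_options()) {
  t <- series$time_min
  arr <- detect_growth_arrest(series$rel_length_pct, t,
                              rate_frac = opts$arrest_rate_frac,
                              consecutive = opts$arrest_consecutive)
  loss <- detect_nucleoid_loss(series$rel_intensity_pct, t,
                               loss_pct = opts$loss_threshold_pct,
                               high_pct = opts$sudden_high_pct,
                               low_pct = opts$sudden_low_pct,
                               sudden_frames = opts$sudden_max_frames,
                               gradual_frames = opts$gradual_min_frames)
  dis <- detect_disintegration(series$coverage, t,
                               cutoff = opts$disintegration_coverage)
  wend <- if (!is.na(loss$time_min)) loss$time_min else Inf
  elong <- nucleoid_elongation_state(series$rel_nucleoid_pct, t, wend,
                                     doubling_time_min = opts$doubling_time_min,
                                     arrest_frac = opts$elong_arrest_frac,
                                     slow_frac = opts$elong_slow_frac)
  rt <- ratio_trend(series$ratio, t, wend,
                    deadband_frac = opts$ratio_deadband_frac)

  # shrinkage: smoothed relative length drops from its running max, judged
  # only while the envelope is still intact
  post <- t >= 0 & (is.na(dis) | t < dis) & series$present
  sm <- .smooth3(series$rel_length_pct)[post]
  sm <- sm[is.finite(sm)]
  shrinkage <- length(sm) > 1 && any(cummax(sm) - sm > opts$shrinkage_pct)

  # membrane features: require the type in >= 2 usable (pre-disintegration)
  # frames; large blobs take precedence
  usable <- series$present & (is.na(dis) | t < dis)
  ft <- series$feature_type[usable]
  tt <- t[usable]
  blobs <- "none"; blob_onset <- NA_real_
  if (sum(ft == "large_blobs") >= 2) {
    blobs <- "large_blobs"; blob_onset <- tt[which(ft == "large_blobs")[1]]
  } else if (sum(ft == "small_foci") >= 2) {
    blobs <- "small_foci"; blob_onset <- tt[which(ft == "small_foci")[1]]
  }

  list(growth_arrest_min = if (arr$degenerate) 0 else arr$time_min,
       degenerate_baseline = arr$degenerate,
       nucleoid_loss_min = loss$time_min,
       nucleoid_loss_mode = loss$mode,
       disintegration_min = dis,
       blobs = blobs, blob_onset_min = blob_onset,
       shrinkage = shrinkage,
       nucleoid_elongation_state = elong,
       ratio_trend = rt$trend,
       decondensation_extent = rt$extent)
}
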