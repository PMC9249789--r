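# End-to-end quantification of a stack: segmentation, tracking, profiling,
# status assignment and per-cell event detection.

#' Quantify a two-channel time-lapse stack
#'
#' Runs the whole measurement chain: Z max-projection if needed,
#' membrane-channel segmentation and overlap tracking, per-frame medial axes
#' and wide-line profiles, cell/nucleoid length, background-corrected
#' nucleoid intensity, membrane coverage and features, per-frame status and
#' population fractions, and per-cell timed events.
#'
#' @param stack a `dbmi_stack` (axes TCYX or TZCYX).
#' @param opts a [dbmi_options()] list.
#' @return object of class `dbmi_analysis`: list with `features` (tidy per
#'   cell x frame table), `events` (per-cell event lists), `status_fractions`,
#'   `tracks`, `cell_ids` (analysed units), `stack_meta`, `opts`.
#' @export
analyze_stack <- function(stack, opts = dbmi_options()) {
  stopifnot(inherits(stack, "dbmi_stack"))
  if (stack$axes == "TZCYX") stack <- max_project(stack)
  d <- stack$data
  nt <- dim(d)[1]
  px <- stack$pixel_size_um
  tf <- stack$treatment_start_frame
  times <- (seq_len(nt) - tf) * stack$frame_interval_min

  labels <- lapply(seq_len(nt), function(j)
    segment_frame(d[j, 1, , ], smooth_sigma_px = opts$smooth_sigma_px,
                  close_radius_px = opts$close_radius_px,
                  min_area_px = opts$min_area_px))
  tracks <- track_cells(labels)
  bg <- lapply(seq_len(nt), function(j)
    list(membrane = estimate_background(d[j, 1, , ], labels[[j]]),
         nucleoid = estimate_background(d[j, 2, , ], labels[[j]])))

  units <- Filter(function(tr) tr$present[1], tracks$tracks)
  if (opts$exclude_border) {
    units <- Filter(function(tr) {
      m <- tr$masks[[1]]
      !(any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) || any(m[, ncol(m)]))
    }, units)
  }

  feats <- list()
  events <- list()
  for (tr in units) {
    ser <- .profile_track(tr, d, bg, times, px, opts)
    ser$cell_id <- tr$cell_id
    feats[[length(feats) + 1]] <- ser
    ev <- cell_events(ser, opts)
    ev$cell_id <- tr$cell_id
    events[[length(events) + 1]] <- ev
  }
  features <- if (length(feats)) do.call(rbind, feats) else NULL

  status_df <- if (!is.null(features)) {
    data.frame(cell_id = features$cell_id, frame = features$frame,
               status = features$status)
  } else data.frame(cell_id = integer(0), frame = integer(0),
                    status = character(0))
  fractions <- if (nrow(status_df)) population_status_fractions(status_df) else NULL

  structure(list(features = features, events = events,
                 status_fractions = fractions, tracks = tracks,
                 cell_ids = vapply(units, function(tr) tr$cell_id, integer(1)),
                 stack_meta = stack[c("pixel_size_um", "frame_interval_min",
                                      "treatment_start_frame")],
                 times = times, opts = opts),
            class = "dbmi_analysis")
}

# Measure one track across all frames.
.profile_track <- function(tr, d, bg, times, px, opts) {
  nt <- length(times)
  length_px <- rep(NA_real_, nt)
  nuc_len <- rep(0, nt)
  intens <- rep(0, nt)
  covered_px <- rep(0, nt)
  feature_type <- rep("none", nt)
  axes <- vector("list", nt)
  prev_poly <- NULL
  for (j in seq_len(nt)) {
    if (!tr$present[j]) next
    mask <- tr$masks[[j]]
    ax <- tryCatch(medial_axis_of(mask, prev = prev_poly),
                   error = function(e) NULL)
    if (is.null(ax)) next
    axes[[j]] <- ax
    prev_poly <- ax$polyline
    length_px[j] <- ax$length_px
    memb <- d[j, 1, , ]; nucl <- d[j, 2, , ]
    prof_nuc <- extract_wide_line_profile(nucl, ax, opts$width_px)
    nuc_len[j] <- measure_nucleoid_length(prof_nuc, bg[[j]]$nucleoid, px,
                                          k = opts$k_sigma,
                                          rel_floor = opts$rel_floor)
    # integrate intensity over a slightly dilated mask so the PSF-blurred
    # tails of the in-cell signal are captured for short cells too
    dmask <- EBImage::imageData(EBImage::dilate(
      EBImage::Image(mask * 1), EBImage::makeBrush(7, "disc"))) > 0.5
    intens[j] <- measure_nucleoid_intensity(dmask, nucl, bg[[j]]$nucleoid)
    peaks <- extract_wide_line_profile(memb, ax, opts$width_px, agg = "max")
    thr <- bg[[j]]$membrane$level + opts$k_sigma * bg[[j]]$membrane$sigma
    covered_px[j] <- sum(peaks > thr)
    ft <- detect_membrane_features(memb, mask, ax,
                                   factor = opts$feature_intensity_factor,
                                   a_blob_px = opts$a_blob_px,
                                   width_px = opts$width_px)
    feature_type[j] <- ft$type
  }
  # membrane coverage: detectable axial extent relative to the largest
  # extent reached so far (a shrunken or partially vanished envelope scores
  # low; an absent cell scores 0)
  ref_len <- cummax(ifelse(is.na(length_px), 0, length_px))
  coverage <- ifelse(ref_len > 0, covered_px / ref_len, 1)
  coverage[!tr$present] <- 0
  coverage <- pmin(coverage, 1)

  tf_idx <- which(times == 0)
  cell_um <- length_px * px
  rel_len <- if (is.finite(cell_um[tf_idx]) && cell_um[tf_idx] > 0)
    normalize_series(cell_um, tf_idx) else rep(NA_real_, nt)
  rel_nuc <- if (nuc_len[tf_idx] > 0) normalize_series(nuc_len, tf_idx)
             else rep(NA_real_, nt)
  rel_int <- if (intens[tf_idx] > 0) normalize_series(intens, tf_idx)
             else rep(NA_real_, nt)
  ratio <- ratio_series(nuc_len, cell_um)

  detectable <- nuc_len > 0
  status <- enforce_status_order(
    classify_status(coverage, detectable, opts$disintegration_coverage))

  data.frame(frame = seq_len(nt), time_min = times,
             present = tr$present, length_um = cell_um,
             rel_length_pct = rel_len, nucleoid_length_um = nuc_len,
             rel_nucleoid_pct = rel_nuc, intensity = intens,
             rel_intensity_pct = rel_int, ratio = ratio,
             coverage = coverage, feature_type = feature_type,
             status = status)
}

#' Per-cell kymographs for an analysed stack
#'
#' @param analysis a [analyze_stack()] result.
#' @param stack the `dbmi_stack` that was analysed.
#' @param cell_ids cells to include (default: all analysed units).
#' @return named list (one entry per cell) of [build_kymograph()] results.
#' @export
analysis_kymographs <- function(analysis, stack, cell_ids = analysis$cell_ids) {
  if (stack$axes == "TZCYX") stack <- max_project(stack)
  out <- list()
  for (tr in analysis$tracks$tracks) {
    if (!tr$cell_id %in% cell_ids) next
    tr$axes <- .track_axes(tr, analysis, stack)
    out[[as.character(tr$cell_id)]] <- build_kymograph(tr, stack,
                                                       analysis$opts$width_px)
  }
  out
}

.track_axes <- function(tr, analysis, stack) {
  nt <- dim(stack$data)[1]
  axes <- vector("list", nt)
  prev <- NULL
  for (j in seq_len(nt)) {
    if (!tr$present[j]) next
    ax <- tryCatch(medial_axis_of(tr$masks[[j]], prev = prev),
                   error = function(e) NULL)
    if (is.null(ax)) next
    axes[[j]] <- ax
    prev <- ax$polyline
  }
  axes
}

#' @export
print.dbmi_analysis <- function(x, ...) {
  cat(sprintf("<dbmi_analysis> %d cell units, %d frames\n",
              length(x$cell_ids), length(x$times)))
  invisible(x)
}
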