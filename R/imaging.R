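# Stack I/O, Z projection, segmentation and tracking.
#
# Stacks are stored as multi-page 16-bit TIFF (pages in T x (Z x) C order)
# with a JSON sidecar (<stem>.json) carrying axes, shape, physical pixel
# size, frame interval and the treatment-start frame.

.stack_scale <- 65535

#' Write a time-lapse stack (and optionally its ground truth) to disk
#'
#' @param stack a `dbmi_stack`.
#' @param path output TIFF path; a metadata sidecar is written next to it
#'   with extension `.json`.
#' @param truth optional ground-truth table written as CSV.
#' @param truth_path CSV path (default: `<stem>_truth.csv`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, truth = NULL, truth_path = NULL) {
  stopifnot(inherits(stack, "dbmi_stack"))
  d <- stack$data
  dm <- dim(d)
  flat <- array(d, c(prod(dm[-c(length(dm) - 1, length(dm))]),
                     dm[length(dm) - 1], dm[length(dm)]))
  pages <- lapply(seq_len(dim(flat)[1]), function(i)
    pmin(pmax(flat[i, , ] / .stack_scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none",
                  reduce = FALSE)
  meta <- list(axes = stack$axes, shape = dm,
               pixel_size_um = stack$pixel_size_um,
               frame_interval_min = stack$frame_interval_min,
               treatment_start_frame = stack$treatment_start_frame,
               intensity_scale = .stack_scale)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    if (is.null(truth_path)) {
      truth_path <- sub("\\.[^.]+$", "_truth.csv", path)
    }
    utils::write.csv(truth, truth_path, row.names = FALSE)
  }
  invisible(path)
}

.sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Read a time-lapse stack
#'
#' Reads a TIFF written by [write_stack()] (or any multi-page TIFF, provided
#' the metadata is supplied via the override arguments). Axes are normalised
#' to T x (Z x) C x Y x X.
#'
#' @param path TIFF path.
#' @param pixel_size_um,frame_interval_min,treatment_start_frame,axes,shape
#'   metadata overrides; required when no sidecar is present.
#' @return a `dbmi_stack`.
#' @export
read_stack <- function(path, pixel_size_um = NULL, frame_interval_min = NULL,
                       treatment_start_frame = NULL, axes = NULL, shape = NULL) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop(sprintf(
                      "cannot read TIFF '%s': %s", path, conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  meta <- list()
  sc <- .sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  pick <- function(override, key) {
    if (!is.null(override)) override
    else if (!is.null(meta[[key]])) meta[[key]]
    else stop(sprintf("metadata field '%s' missing: no sidecar value and no override given", key))
  }
  axes <- pick(axes, "axes")
  pixel_size_um <- pick(pixel_size_um, "pixel_size_um")
  frame_interval_min <- pick(frame_interval_min, "frame_interval_min")
  treatment_start_frame <- pick(treatment_start_frame, "treatment_start_frame")
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else .stack_scale
  if (!axes %in% c("TCYX", "TZCYX")) {
    stop(sprintf("unsupported axes '%s' (expected TCYX or TZCYX)", axes))
  }
  if (is.null(shape)) shape <- meta$shape
  ci <- nchar(axes) - 2L
  if (is.null(shape)) stop("stack shape unknown: supply 'shape' or a sidecar")
  if (shape[ci] < 2) {
    stop(sprintf("expected 2 channels (membrane, nucleoid), found %d", shape[ci]))
  }
  if (prod(shape[seq_len(ci)]) != length(pages)) {
    stop(sprintf("page count %d does not match declared shape", length(pages)))
  }
  lead <- shape[seq_len(ci)]
  d <- array(0, shape)
  # pages are written in column-major order over the leading axes (T fastest)
  lead_idx <- arrayInd(seq_along(pages), lead)
  for (p in seq_along(pages)) {
    pos <- lead_idx[p, ]
    if (ci == 2) d[pos[1], pos[2], , ] <- pages[[p]]
    else d[pos[1], pos[2], pos[3], , ] <- pages[[p]]
  }
  structure(list(data = d * scale, axes = axes,
                 pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min,
                 treatment_start_frame = treatment_start_frame),
            class = "dbmi_stack")
}

#' Maximum-intensity projection over Z
#'
#' Each output pixel is the maximum over the Z slices of that pixel. Stacks
#' without a Z axis are returned unchanged with a warning.
#'
#' @param stack a `dbmi_stack` with axes `TZCYX` (or `TCYX`).
#' @return a `dbmi_stack` with axes `TCYX`.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "dbmi_stack"))
  if (stack$axes == "TCYX") {
    warning("stack has no Z axis; returning it unchanged")
    return(stack)
  }
  d <- stack$data
  dm <- dim(d)
  out <- array(0, dm[-2])
  for (t in seq_len(dm[1])) for (ch in seq_len(dm[3])) {
    out[t, ch, , ] <- apply(d[t, , ch, , , drop = FALSE], c(4, 5), max)
  }
  stack$data <- out
  stack$axes <- "TCYX"
  stack
}

#' @export
print.dbmi_stack <- function(x, ...) {
  cat(sprintf("<dbmi_stack> axes %s, dim [%s], %g um/px, %g min/frame, treatment at frame %d\n",
              x$axes, paste(dim(x$data), collapse = "x"), x$pixel_size_um,
              x$frame_interval_min, x$treatment_start_frame))
  invisible(x)
}

#' Segment cell units in a membrane-channel frame
#'
#' Gaussian smoothing, Otsu threshold, morphological closing, hole filling
#' (the capsule interior is recovered from its outline), small-object removal
#' and connected-component labelling.
#'
#' @param img 2-D membrane-channel image (matrix, counts).
#' @param smooth_sigma_px pre-smoothing sigma.
#' @param close_radius_px radius of the closing brush.
#' @param min_area_px objects smaller than this are discarded.
#' @return integer label matrix (0 = background) with one label per cell
#'   unit.
#' @export
segment_frame <- function(img, smooth_sigma_px = 1, close_radius_px = 2,
                          min_area_px = 100) {
  stopifnot(is.matrix(img))
  # clip the brightest pixels (membrane foci/blobs) so the Otsu threshold
  # separates background from membrane, not membrane from blob; the cap is
  # value-based (background median + 60% of the dynamic range) so it works
  # on sparse and noiseless frames alike
  med <- stats::median(img)
  rng <- range(img)
  if (diff(rng) <= 0) return(matrix(0L, nrow(img), ncol(img)))
  # a frame with no signal well above the background noise floor is blank
  if (rng[2] <= med + 8 * stats::mad(img)) {
    return(matrix(0L, nrow(img), ncol(img)))
  }
  x <- (img - rng[1]) / diff(rng)
  if (smooth_sigma_px > 0) x <- EBImage::gblur(x, sigma = smooth_sigma_px)
  thr <- .otsu_lower(x)
  bw <- EBImage::Image((x > thr) * 1)
  bw <- EBImage::closing(bw, EBImage::makeBrush(2 * close_radius_px + 1, "disc"))
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::imageData(EBImage::bwlabel(bw))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px)
  # canonical label order: by centroid, top-to-bottom then left-to-right
  if (length(keep) > 1) {
    cy <- vapply(keep, function(l) mean(which(lab == l, arr.ind = TRUE)[, 1]),
                 numeric(1))
    cx <- vapply(keep, function(l) mean(which(lab == l, arr.ind = TRUE)[, 2]),
                 numeric(1))
    keep <- keep[order(round(cy / 5), cx)]
  }
  out <- matrix(0L, nrow(img), ncol(img))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

# Lower boundary of a three-class Otsu split. Membrane images have up to
# three intensity populations (background, membrane outline, bright
# foci/blobs); a single Otsu threshold can land between membrane and blob,
# collapsing the mask. Maximising the three-class between-class variance and
# keeping the background/membrane boundary is robust to arbitrarily bright
# features. Falls back to the classic two-class threshold when the
# three-class fit degenerates.
.otsu_lower <- function(x, nbins = 256) {
  h <- tabulate(pmin(pmax(floor(x * nbins) + 1L, 1L), nbins), nbins)
  p <- h / sum(h)
  cp <- cumsum(p)
  cm <- cumsum(p * seq_len(nbins))
  best <- -Inf; b1 <- NA_integer_
  for (t1 in 1:(nbins - 2)) {
    if (cp[t1] <= 0) next
    t2 <- (t1 + 1):(nbins - 1)
    w1 <- cp[t1]; m1 <- cm[t1] / w1
    w2 <- cp[t2] - cp[t1]
    w3 <- 1 - cp[t2]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    m2 <- (cm[t2] - cm[t1]) / w2
    m3 <- (cm[nbins] - cm[t2]) / w3
    obj <- w1 * m1^2 + w2 * m2^2 + w3 * m3^2
    obj[!ok] <- -Inf
    i <- which.max(obj)
    if (obj[i] > best) {
      best <- obj[i]
      b1 <- t1
    }
  }
  two <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  if (is.na(b1)) return(two)
  lower <- b1 / nbins
  # guard against a degenerate lower boundary hugging the background mode
  if (lower < 0.02) return(two)
  # adopt the lower boundary only when a distinct very-bright class exists
  # (otherwise the two-class threshold is tighter and more accurate)
  fg <- x[x > lower]
  blobby <- length(fg) > 50 &&
    stats::quantile(fg, 0.99) > 1.8 * stats::quantile(fg, 0.80)
  if (blobby) min(lower, two) else two
}

#' Track segmented cells through a movie by greedy mask overlap
#'
#' Labels are propagated frame to frame by maximum pixel overlap; a track
#' keeps its identity through divisions (septa never split the unit defined
#' at the initial frame), unmatched tracks are marked absent and never
#' resurrected, and unmatched objects open new tracks.
#'
#' @param labels list of integer label matrices, one per frame.
#' @return object of class `dbmi_tracks`: list of tracks, each with
#'   `cell_id`, `present` (logical per frame), and `masks` (list of logical
#'   matrices or NULL).
#' @export
track_cells <- function(labels) {
  nt <- length(labels)
  stopifnot(nt >= 1)
  tracks <- list()
  prev_map <- integer(0)   # label in previous frame -> track index
  first <- labels[[1]]
  for (l in seq_len(max(first, 0))) {
    tracks[[length(tracks) + 1]] <- list(cell_id = length(tracks) + 1L,
                                         present = c(TRUE, rep(FALSE, nt - 1)),
                                         masks = vector("list", nt))
    tracks[[length(tracks)]]$masks[[1]] <- first == l
    prev_map[l] <- length(tracks)
  }
  for (j in seq_len(nt)[-1]) {
    lab <- labels[[j]]
    nlab <- max(lab, 0)
    cur_map <- integer(nlab)
    if (nlab > 0 && length(prev_map) > 0) {
      prev_lab <- labels[[j - 1]]
      both <- prev_lab > 0 & lab > 0
      if (any(both)) {
        ov <- table(prev = prev_lab[both], cur = lab[both])
        pairs <- as.data.frame(ov, stringsAsFactors = FALSE)
        pairs <- pairs[pairs$Freq > 0, ]
        pairs <- pairs[order(-pairs$Freq), ]
        used_prev <- logical(length(prev_map))
        for (k in seq_len(nrow(pairs))) {
          pl <- as.integer(pairs$prev[k]); cl <- as.integer(pairs$cur[k])
          ti <- prev_map[pl]
          if (is.na(ti) || ti == 0 || used_prev[pl] || cur_map[cl] != 0) next
          cur_map[cl] <- ti
          used_prev[pl] <- TRUE
        }
      }
    }
    for (l in seq_len(nlab)) {
      if (cur_map[l] == 0) {               # new object -> new track
        tracks[[length(tracks) + 1]] <- list(cell_id = length(tracks) + 1L,
                                             present = rep(FALSE, nt),
                                             masks = vector("list", nt))
        cur_map[l] <- length(tracks)
      }
      ti <- cur_map[l]
      tracks[[ti]]$present[j] <- TRUE
      tracks[[ti]]$masks[[j]] <- lab == l
    }
    prev_map <- integer(nlab)
    for (l in seq_len(nlab)) prev_map[l] <- cur_map[l]
  }
  structure(list(tracks = tracks, n_frames = nt), class = "dbmi_tracks")
}

#' @export
print.dbmi_tracks <- function(x, ...) {
  cat(sprintf("<dbmi_tracks> %d tracks over %d frames\n",
              length(x$tracks), x$n_frames))
  invisible(x)
}

#' Medial axis of a single cell mask
#'
#' Projects the mask pixels on their principal axis, takes the transverse
#' centroid in 1-px axial bins and smooths the resulting pole-to-pole
#' polyline. Orientation is stabilised against a previous-frame axis when
#' given (the pole order minimising end-point displacement is kept). Nearly
#' isotropic masks (no clear long axis) are flagged degenerate.
#'
#' @param mask logical matrix (single connected component).
#' @param prev optional previous-frame polyline for orientation matching.
#' @return list with `polyline` (n x 2 matrix of x, y pixel coordinates,
#'   ordered pole to pole), `length_px` (arc length), and `degenerate` flag.
#' @export
medial_axis_of <- function(mask, prev = NULL) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 4) stop("mask too small for a medial axis")
  pts <- cbind(x = idx[, 2], y = idx[, 1])
  ctr <- colMeans(pts)
  pc <- prcomp(pts, center = TRUE)
  axis_dir <- pc$rotation[, 1]
  proj <- (pts[, 1] - ctr[1]) * axis_dir[1] + (pts[, 2] - ctr[2]) * axis_dir[2]
  tproj <- (pts[, 1] - ctr[1]) * -axis_dir[2] + (pts[, 2] - ctr[2]) * axis_dir[1]
  degenerate <- diff(range(proj)) < 1.2 * diff(range(tproj))
  bins <- floor(proj - min(proj))
  cen_t <- tapply(tproj, bins, mean)
  cen_p <- tapply(proj, bins, mean)
  ord <- order(as.numeric(names(cen_t)))
  cen_t <- as.numeric(cen_t[ord]); cen_p <- as.numeric(cen_p[ord])
  if (length(cen_t) >= 5) {
    cen_t <- as.numeric(stats::filter(cen_t, rep(1 / 5, 5), sides = 2))
  }
  # fill NA ends (running-mean window overhangs) from the nearest value
  if (anyNA(cen_t)) {
    ok <- which(!is.na(cen_t))
    cen_t[seq_len(min(ok) - 1)] <- cen_t[min(ok)]
    cen_t[seq(max(ok) + 1, length.out = length(cen_t) - max(ok))] <- cen_t[max(ok)]
  }
  poly <- cbind(x = ctr[1] + cen_p * axis_dir[1] - cen_t * axis_dir[2],
                y = ctr[2] + cen_p * axis_dir[2] + cen_t * axis_dir[1])
  if (!is.null(prev)) {
    d_same <- sum((poly[1, ] - prev[1, ])^2) +
      sum((poly[nrow(poly), ] - prev[nrow(prev), ])^2)
    d_flip <- sum((poly[1, ] - prev[nrow(prev), ])^2) +
      sum((poly[nrow(poly), ] - prev[1, ])^2)
    if (d_flip < d_same) poly <- poly[nrow(poly):1, , drop = FALSE]
  }
  seglen <- sqrt(rowSums(diff(poly)^2))
  list(polyline = poly, length_px = sum(seglen), degenerate = degenerate)
}
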