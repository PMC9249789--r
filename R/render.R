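# Rendering of ground-truth trajectories into two-channel image stacks.
#
# Geometry convention: pixel-centred 0-based coordinates are used in all
# documentation; internally R's 1-based matrix indices are offset by one.
# Cells are laid out horizontally, one per row band, anchored at their
# mid-point so growth extends symmetrically from both poles. The membrane is
# a 2-px-wide capsule outline drawn just inside the nominal cell boundary so
# that, after PSF blur, the half-maximum axial extent of the membrane channel
# matches the true cell length; the nucleoid fills the axial segments across
# 60% of the cell width.

#' Render trajectories into a two-channel time-lapse stack
#'
#' Draws each frame (channel 0 = membrane dye, channel 1 = nucleoid dye),
#' applies a Gaussian PSF, then adds background and Poisson + Gaussian read
#' noise. Rendering is deterministic given `config$rng_seed`.
#'
#' @param trajs a [simulate_population()] result.
#' @param config a [scene_config()]; defaults to the one stored in `trajs`.
#' @return list with `stack` (a `dbmi_stack`: array T x C x Y x X plus
#'   metadata) and `truth` (the [trajectory_truth()] table).
#' @export
render_timelapse <- function(trajs, config = trajs$config) {
  stopifnot(inherits(trajs, "dbmi_trajectories"))
  px <- config$pixel_size_um
  times <- scene_times(config)
  nt <- length(times)
  n <- length(trajs$cells)
  rpx <- config$cell_radius_um / px

  row_h <- ceiling(2 * rpx + 20)
  shape <- config$image_shape_px
  if (is.null(shape)) {
    max_l <- if (n) max(vapply(trajs$cells, function(cl) max(cl$length_um),
                               numeric(1))) else 3
    shape <- c(row_h * max(n, 1) + 16, 2 * ceiling(max_l / px / 2) + 40)
  }
  ny <- shape[1]; nx <- shape[2]

  mem <- array(0, c(nt, ny, nx))
  nuc <- array(0, c(nt, ny, nx))
  for (j in seq_len(nt)) {
    for (i in seq_len(n)) {
      cl <- trajs$cells[[i]]
      yc <- 8 + row_h * (i - 1) + row_h / 2
      drawn <- .draw_cell(cl, j, times[j], yc, nx, ny, rpx, px, config)
      if (is.null(drawn)) next
      mem[j, drawn$rows, drawn$cols] <- mem[j, drawn$rows, drawn$cols] + drawn$mem
      nuc[j, drawn$rows, drawn$cols] <- nuc[j, drawn$rows, drawn$cols] + drawn$nuc
    }
  }

  sig_px <- config$psf_sigma_um / px
  out <- array(0, c(nt, 2, ny, nx))
  for (j in seq_len(nt)) {
    m <- mem[j, , ]; u <- nuc[j, , ]
    if (sig_px > 0) {
      m <- EBImage::gblur(m, sigma = sig_px)
      u <- EBImage::gblur(u, sigma = sig_px)
    }
    out[j, 1, , ] <- m + config$background_level
    out[j, 2, , ] <- u + config$background_level
  }
  out <- with_seed(config$rng_seed, .apply_noise(out, config))

  stack <- structure(list(data = out, axes = "TCYX",
                          pixel_size_um = px,
                          frame_interval_min = config$frame_interval_min,
                          treatment_start_frame = treatment_frame(config)),
                     class = "dbmi_stack")
  list(stack = stack, truth = trajectory_truth(trajs))
}

.apply_noise <- function(arr, config) {
  if (config$poisson_scale > 0) {
    lam <- pmax(arr, 0) * config$poisson_scale
    arr[] <- stats::rpois(length(lam), lam) / config$poisson_scale
  }
  if (config$gaussian_read_noise > 0) {
    arr <- arr + stats::rnorm(length(arr), 0, config$gaussian_read_noise)
  }
  pmax(arr, 0)
}

# Draw one cell into a local patch; returns patch + target indices, or NULL
# if the cell has fully vanished.
.draw_cell <- function(cl, j, t, yc, nx, ny, rpx, px, config) {
  L <- cl$length_um[j] / px                 # axial extent, px
  xc <- nx / 2
  x0 <- xc - L / 2; x1 <- xc + L / 2        # pole positions
  pad <- ceiling(rpx + 8)
  c0 <- floor(x0) - pad; c1 <- ceiling(x1) + pad
  r0 <- floor(yc - rpx) - pad; r1 <- ceiling(yc + rpx) + pad
  if (c0 < 1 || c1 > nx || r0 < 1 || r1 > ny) {
    stop(sprintf("cell %d at frame %d does not fit the %dx%d field",
                 cl$cell_id, j, ny, nx))
  }
  cols <- c0:c1; rows <- r0:r1
  xx <- matrix(cols, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  yy <- matrix(rows, nrow = length(rows), ncol = length(cols))

  # distance to the capsule centreline (poles inset by the radius)
  p0 <- x0 + rpx; p1 <- x1 - rpx
  if (p1 < p0) { p0 <- p1 <- xc }
  dx <- pmax(0, pmax(p0 - xx, xx - p1))
  d <- sqrt(dx^2 + (yy - yc)^2)

  A <- config$membrane_amplitude
  ev <- cl$events
  disintegrated <- cl$status[j] == "disintegrated"

  band <- d >= rpx - 3 & d <= rpx - 1
  memp <- ifelse(band, A, 0)

  # axial coordinate, um from the left pole
  u <- (xx - x0) * px

  if (!disintegrated) {
    # septa at division sites (transverse lines through the interior)
    if (length(cl$divisions)) {
      dim_fac <- 1
      if (ev$membrane_feature == "septal_dimming" && !is.na(ev$membrane_feature_onset) &&
          t >= ev$membrane_feature_onset) {
        dim_fac <- exp(-(t - ev$membrane_feature_onset) / 10)
      }
      half_w <- if (ev$membrane_feature == "thick_septa" &&
                    !is.na(ev$membrane_feature_onset) &&
                    t >= ev$membrane_feature_onset) 2 else 1
      for (k in seq_along(cl$divisions)) {
        if (t >= cl$divisions[k]) {
          for (fr in cl$septa_frac[[k]]) {
            xs <- x0 + fr * L
            sep <- abs(xx - xs) <= half_w & abs(yy - yc) <= rpx - 1
            memp[sep] <- pmax(memp[sep], A * dim_fac)
          }
        }
      }
    }
    # membrane foci / blobs
    ft <- ev$membrane_feature
    if (ft %in% c("small_foci", "large_blobs") &&
        !is.na(ev$membrane_feature_onset) && t >= ev$membrane_feature_onset) {
      nf <- if (ft == "small_foci") 3 else 2
      frad <- if (ft == "small_foci") 1.0 else 4.0
      famp <- if (ft == "small_foci") 3 * A else 0.9 * A
      for (k in seq_len(nf)) {
        fx <- x0 + cl$feature_anchor[k] * L
        fy <- yc + cl$feature_side[k] * (rpx - 2)
        spot <- (xx - fx)^2 + (yy - fy)^2 <= frad^2
        memp[spot] <- memp[spot] + famp
      }
    }
  } else {
    # envelope remnant: a contiguous ~35% of the axial extent survives
    keep <- if (cl$keep_side == "left") u <= 0.35 * cl$length_um[j]
            else u >= 0.65 * cl$length_um[j]
    memp <- ifelse(keep, memp * 0.8, 0)
  }

  nucp <- matrix(0, nrow(xx), ncol(xx))
  if (!disintegrated && !is.null(cl$nucleoid_segments[[j]]) &&
      nrow(cl$nucleoid_segments[[j]]) > 0) {
    segs <- cl$nucleoid_segments[[j]]
    amp <- config$nucleoid_amplitude * cl$intensity_fraction[j]
    hw <- px / 2
    # anti-aliased edges: pixel weight = covered fraction, so segment
    # boundaries and the integrated intensity are sub-pixel accurate
    wv <- pmin(pmax(0.6 * rpx - abs(yy - yc) + 0.5, 0), 1)
    for (k in seq_len(nrow(segs))) {
      wax <- (pmin(u + hw, segs[k, 2]) - pmax(u - hw, segs[k, 1])) / px
      wax <- pmin(pmax(wax, 0), 1)
      nucp <- pmax(nucp, amp * wax * wv)
    }
  }
  list(rows = rows, cols = cols, mem = memp, nuc = nucp)
}
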