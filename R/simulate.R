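#' Simulate single-cell trajectories for a compound preset
#'
#' Generates ground-truth rod-cell trajectories on the acquisition time grid
#' (two pre-treatment frames, then one frame every `frame_interval_min` up to
#' `duration_min`). Cells elongate exponentially at the configured doubling
#' time until the preset's events fire: growth arrest (abrupt, gradual or with
#' shrinkage), sudden or gradual loss of nucleoid-dye fluorescence, envelope
#' disintegration, nucleoid extension arrest/slow-down, and decondensation.
#' Onsets given as a range are sampled per cell on the frame grid.
#'
#' @param preset a [drug_response_preset()] or preset name (see
#'   [get_preset()]).
#' @param n_cells number of cell units (0 allowed).
#' @param config a [scene_config()].
#' @param seed integer seed; trajectories are reproducible given the seed.
#' @return an object of class `dbmi_trajectories`: a list with elements
#'   `cells` (one trajectory per cell), `preset`, `config`, `seed`. Each cell
#'   trajectory carries per-frame `time_min`, `length_um`,
#'   `nucleoid_segments` (list of 2-column start/end matrices, um from the
#'   left pole), `nucleoid_length_um`, `intensity_fraction`, `status`
#'   (intact/no_nucleoid/disintegrated), `divisions` (times), and the
#'   ground-truth `events` list used by the test oracles.
#' @export
simulate_population <- function(preset, n_cells, config = scene_config(),
                                seed = 1L) {
  if (is.character(preset)) preset <- get_preset(preset)
  stopifnot(inherits(preset, "dbmi_preset"), inherits(config, "dbmi_scene_config"),
            n_cells >= 0)
  times <- scene_times(config)
  cells <- with_seed(seed, lapply(seq_len(n_cells), function(i) {
    .simulate_cell(i, preset, config, times)
  }))
  structure(list(cells = cells, preset = preset, config = config,
                 seed = as.integer(seed)),
            class = "dbmi_trajectories")
}

# Snap a time to the acquisition frame grid.
.snap <- function(t, interval) round(t / interval) * interval

.simulate_cell <- function(cell_id, preset, config, times) {
  dt <- config$frame_interval_min
  r <- log(2) / config$doubling_time_min
  nt <- length(times)

  L0 <- stats::runif(1, 2.0, 2.6)           # initial cell length, um
  rho0 <- stats::runif(1, 0.50, 0.60)       # baseline nucleoid/cell ratio
  n_seg <- sample(1:2, 1)

  # --- per-cell event times ------------------------------------------------
  arrest <- NA_real_
  ga <- preset$growth_arrest_onset
  if (!all(is.na(ga))) {
    arrest <- if (length(ga) == 2) {
      sample(seq(ga[1], ga[2], by = dt), 1)
    } else .snap(ga, dt)
  }
  loss <- NA_real_
  if (!is.na(preset$loss_after_arrest_min)) {
    loss <- arrest + .snap(preset$loss_after_arrest_min, dt)
  } else if (!all(is.na(preset$nucleoid_loss_onset))) {
    loss <- .snap(preset$nucleoid_loss_onset, dt)
  }
  disint <- NA_real_
  if (!all(is.na(preset$disintegration_lag))) {
    lag <- if (length(preset$disintegration_lag) > 1)
      sample(preset$disintegration_lag, 1) else preset$disintegration_lag
    disint <- loss + .snap(lag, dt)
  }
  gradual_affected <- preset$nucleoid_loss_mode == "gradual" &&
    stats::runif(1) < preset$gradual_loss_fraction
  feature <- preset$membrane_feature
  feature_onset <- if (feature == "none") NA_real_ else {
    if (!is.na(preset$membrane_feature_onset)) preset$membrane_feature_onset
    else arrest + dt    # "after arrest" default, e.g. septal dimming
  }

  # --- cell length ---------------------------------------------------------
  length_um <- numeric(nt)
  length_um[1] <- L0
  for (j in 2:nt) {
    t0 <- times[j - 1]; t1 <- times[j]
    g <- 1
    if (t0 >= 0) {                          # post-treatment growth modifiers
      if (preset$arrest_mode == "abrupt" && !is.na(arrest) && t0 >= arrest) {
        g <- 0
      } else if (preset$arrest_mode == "gradual") {
        g <- preset$growth_attenuation
        if (is.finite(preset$growth_decay_halflife_min)) {
          g <- g * 2^(-(t0 + t1) / 2 / preset$growth_decay_halflife_min)
        }
      } else if (preset$arrest_mode == "shrink" && !is.na(arrest) && t0 >= arrest) {
        length_um[j] <- length_um[j - 1] * (1 - preset$shrink_rate_per_min * dt)
        next
      }
    }
    length_um[j] <- length_um[j - 1] * exp(r * g * dt)
  }

  # --- divisions (cosmetic septa; the tracked unit is never split) ---------
  divisions <- numeric(0)
  septa_frac <- list()
  k <- 1
  for (j in seq_len(nt)) {
    if (length_um[j] >= L0 * 2^k) {
      divisions <- c(divisions, times[j])
      # first septum at midcell, later rounds at the quarter positions
      septa_frac[[k]] <- if (k == 1) 0.5 else c(0.25, 0.75)
      k <- k + 1
    }
  }

  # --- nucleoid length and condensation ------------------------------------
  tf <- which(times == 0)
  Lt0 <- length_um[tf]
  nucleoid_um <- rho0 * length_um           # pre-treatment / factor = 1
  post <- times >= 0
  if (!is.na(preset$decondensation_target_ratio)) {
    rho <- preset$decondensation_target_ratio -
      (preset$decondensation_target_ratio - rho0) *
      exp(-pmax(times, 0) / preset$decondensation_tau_min)
    nucleoid_um[post] <- rho[post] * length_um[post]
  } else if (preset$nucleoid_elongation_factor != 1) {
    nucleoid_um[post] <- rho0 * Lt0 *
      (length_um[post] / Lt0)^preset$nucleoid_elongation_factor
  }
  nucleoid_um <- pmin(nucleoid_um, 0.98 * length_um)

  # --- intensity fraction (of the t = 0 value) -----------------------------
  intensity <- rep(1, nt)
  if (gradual_affected) {
    fl <- preset$gradual_loss_floor
    intensity[post] <- fl + (1 - fl) * exp(-times[post] / preset$gradual_loss_tau_min)
  }
  if (!is.na(loss)) intensity[times >= loss] <- 0.02

  # --- status (monotone: intact -> no_nucleoid -> disintegrated) -----------
  status <- rep("intact", nt)
  if (!is.na(loss)) status[times >= loss] <- "no_nucleoid"
  if (!is.na(disint)) status[times >= disint] <- "disintegrated"

  # --- nucleoid segments ---------------------------------------------------
  segs <- vector("list", nt)
  nseg_t <- n_seg
  div_i <- 0
  for (j in seq_len(nt)) {
    if (div_i < length(divisions) && times[j] >= divisions[div_i + 1]) {
      div_i <- div_i + 1
      nseg_t <- min(nseg_t * 2L, 4L)
    }
    L <- length_um[j]
    N <- nucleoid_um[j]
    if (!is.na(loss) && times[j] >= loss) {
      # geometry frozen at loss (fluorescence residual only), clamped to the
      # current cell length in case the cell shrinks afterwards
      s <- segs[[max(j - 1, 1)]]
      s[] <- pmin(pmax(s, 0), L)
      s <- s[s[, 2] > s[, 1], , drop = FALSE]
      segs[[j]] <- s
      next
    }
    len <- N / nseg_t
    ctr <- L * (2 * seq_len(nseg_t) - 1) / (2 * nseg_t)
    s <- cbind(ctr - len / 2, ctr + len / 2)
    if (preset$irregular_nucleoid && times[j] > 0) {
      s <- s + matrix(stats::runif(length(s), -0.1, 0.1), ncol = 2)
      s[, 2] <- pmax(s[, 2], s[, 1] + 0.05)
    }
    s[] <- pmin(pmax(s, 0), L)
    segs[[j]] <- s
  }

  nuc_len <- vapply(seq_len(nt), function(j) sum(segs[[j]][, 2] - segs[[j]][, 1]),
                    numeric(1))
  detectable_len <- ifelse(intensity > 0.1, nuc_len, 0)

  shrinkage <- preset$arrest_mode == "shrink"
  list(cell_id = cell_id, time_min = times, length_um = length_um,
       nucleoid_segments = segs, nucleoid_length_um = detectable_len,
       intensity_fraction = intensity, status = status,
       divisions = divisions, septa_frac = septa_frac,
       base_ratio = rho0, L0 = L0,
       keep_side = sample(c("left", "right"), 1),
       feature_anchor = stats::runif(3, 0.15, 0.85),
       feature_side = sample(c(-1, 1), 3, replace = TRUE),
       events = list(arrest_min = arrest, arrest_mode = preset$arrest_mode,
                     nucleoid_loss_min = loss,
                     nucleoid_loss_mode = if (!is.na(loss)) "sudden"
                     else if (gradual_affected) "gradual" else "none",
                     disintegration_min = disint,
                     membrane_feature = feature,
                     membrane_feature_onset = feature_onset,
                     shrinkage = shrinkage))
}

#' Ground-truth table of a simulated population
#'
#' @param trajs a `dbmi_trajectories` object.
#' @return tidy data frame, one row per (cell_id, frame): `time_min`,
#'   `length_um`, `nucleoid_length_um`, `intensity_fraction`, `status`.
#' @export
trajectory_truth <- function(trajs) {
  stopifnot(inherits(trajs, "dbmi_trajectories"))
  if (!length(trajs$cells)) {
    return(data.frame(cell_id = integer(0), frame = integer(0),
                      time_min = numeric(0), length_um = numeric(0),
                      nucleoid_length_um = numeric(0),
                      intensity_fraction = numeric(0), status = character(0)))
  }
  do.call(rbind, lapply(trajs$cells, function(cl) {
    data.frame(cell_id = cl$cell_id, frame = seq_along(cl$time_min),
               time_min = cl$time_min, length_um = cl$length_um,
               nucleoid_length_um = cl$nucleoid_length_um,
               intensity_fraction = cl$intensity_fraction,
               status = cl$status)
  }))
}

#' Ground-truth event times of a simulated population
#'
#' @param trajs a `dbmi_trajectories` object.
#' @return data frame, one row per cell, with the per-cell sampled event
#'   times (minutes after treatment; NA where the preset defines no event).
#' @export
trajectory_events <- function(trajs) {
  do.call(rbind, lapply(trajs$cells, function(cl) {
    ev <- cl$events
    data.frame(cell_id = cl$cell_id, arrest_min = ev$arrest_min,
               arrest_mode = ev$arrest_mode,
               nucleoid_loss_min = ev$nucleoid_loss_min,
               nucleoid_loss_mode = ev$nucleoid_loss_mode,
               disintegration_min = ev$disintegration_min,
               membrane_feature = ev$membrane_feature,
               membrane_feature_onset = ev$membrane_feature_onset,
               shrinkage = ev$shrinkage)
  }))
}

#' @export
print.dbmi_trajectories <- function(x, ...) {
  cat(sprintf("<dbmi_trajectories> %d cells, preset '%s', %d frames (%g min grid)\n",
              length(x$cells), x$preset$name,
              length(scene_times(x$config)), x$config$frame_interval_min))
  invisible(x)
}
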