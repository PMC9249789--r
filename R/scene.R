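#' Acquisition and rendering configuration
#'
#' Bundles the acquisition geometry and noise model used by the simulator and
#' renderer. Defaults mirror the imaging convention the quantification assumes:
#' 0.065 um/px (so a 20-px wide line spans 1.3 um), 3-min frame interval, two
#' pre-treatment frames, and a 60-min post-treatment movie.
#'
#' @param pixel_size_um physical pixel size (um/px).
#' @param frame_interval_min time between frames (min).
#' @param n_pretreatment_frames frames acquired before treatment start.
#' @param duration_min post-treatment imaging duration (min).
#' @param psf_sigma_um Gaussian point-spread-function sigma (um).
#' @param background_level camera background offset (counts).
#' @param membrane_amplitude,nucleoid_amplitude peak signal above background
#'   (counts) for the two dyes.
#' @param poisson_scale photon conversion: noise is
#'   `rpois(signal * scale) / scale`; 0 disables shot noise.
#' @param gaussian_read_noise read-noise standard deviation (counts); 0
#'   disables.
#' @param rng_seed seed used for rendering noise (integer).
#' @param image_shape_px c(rows, cols) or NULL to auto-size to the population.
#' @param cell_radius_um rod cell radius (um); B. subtilis rods are ~0.85 um
#'   wide.
#' @param doubling_time_min untreated doubling time (min); the control growth
#'   rate.
#' @return an object of class `dbmi_scene_config`.
#' @export
scene_config <- function(pixel_size_um = 0.065,
                         frame_interval_min = 3,
                         n_pretreatment_frames = 2,
                         duration_min = 60,
                         psf_sigma_um = 0.1,
                         background_level = 100,
                         membrane_amplitude = 600,
                         nucleoid_amplitude = 500,
                         poisson_scale = 0.5,
                         gaussian_read_noise = 3,
                         rng_seed = 1L,
                         image_shape_px = NULL,
                         cell_radius_um = 0.42,
                         doubling_time_min = 30) {
  stopifnot(pixel_size_um > 0, frame_interval_min > 0,
            n_pretreatment_frames >= 1, duration_min >= frame_interval_min,
            psf_sigma_um >= 0, background_level >= 0, poisson_scale >= 0,
            gaussian_read_noise >= 0, doubling_time_min > 0)
  structure(list(
    pixel_size_um = pixel_size_um,
    frame_interval_min = frame_interval_min,
    n_pretreatment_frames = n_pretreatment_frames,
    duration_min = duration_min,
    psf_sigma_um = psf_sigma_um,
    background_level = background_level,
    membrane_amplitude = membrane_amplitude,
    nucleoid_amplitude = nucleoid_amplitude,
    poisson_scale = poisson_scale,
    gaussian_read_noise = gaussian_read_noise,
    rng_seed = as.integer(rng_seed),
    image_shape_px = image_shape_px,
    cell_radius_um = cell_radius_um,
    doubling_time_min = doubling_time_min
  ), class = "dbmi_scene_config")
}

# Frame time grid, minutes relative to treatment start (t = 0 is the
# treatment-start frame; pre-treatment frames sit at negative times).
scene_times <- function(config) {
  pre <- -rev(seq_len(config$n_pretreatment_frames)) * config$frame_interval_min
  post <- seq(0, config$duration_min, by = config$frame_interval_min)
  c(pre, post)
}

# Index (1-based) of the treatment-start frame.
treatment_frame <- function(config) config$n_pretreatment_frames + 1L

# Evaluate-with-seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
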