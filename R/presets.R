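.moa_classes <- c("membrane", "wall", "protein", "dna", "rna", "control")
.moa_subclasses <- c("pore_former", "depolarizer", "transpeptidation_inhibitor",
                     "lipid_II_inhibitor", "rnap_inhibitor",
                     "transcription_complex_inhibitor", "none")
.membrane_features <- c("none", "small_foci", "large_blobs", "septal_dimming",
                        "thick_septa")

#' Construct a drug-response preset
#'
#' A preset is the ground truth driving the simulator: it encodes when and how
#' a compound class arrests growth, abolishes or erodes nucleoid-dye
#' fluorescence, disintegrates the cell envelope, changes the
#' nucleoid-extension rate or condensation state, and which membrane features
#' (foci, blobs, septal changes) it induces.
#'
#' Onset times are minutes after treatment start (t = 0). A length-2
#' `growth_arrest_onset` is an inclusive range sampled per cell on the frame
#' grid; `disintegration_lag` may be a vector of allowed lags (minutes after
#' nucleoid loss) sampled per cell.
#'
#' @param name compound identifier.
#' @param moa_class one of membrane, wall, protein, dna, rna, control.
#' @param moa_subclass mechanism sub-class (see [classify_cell()] level 3).
#' @param growth_arrest_onset min after treatment (scalar, range, or NA).
#' @param arrest_mode one of abrupt, gradual, shrink, none.
#' @param loss_after_arrest_min for wall-type presets: sudden nucleoid loss
#'   this many minutes after the (per-cell) arrest time.
#' @param nucleoid_loss_onset min after treatment (NA if none or tied to
#'   arrest via `loss_after_arrest_min`).
#' @param nucleoid_loss_mode sudden, gradual or none.
#' @param gradual_loss_fraction fraction of cells showing the gradual
#'   intensity decline.
#' @param gradual_loss_floor asymptotic intensity fraction of the decline.
#' @param gradual_loss_tau_min e-folding time of the decline (min).
#' @param disintegration_lag min after nucleoid loss (vector of choices or NA).
#' @param nucleoid_elongation_factor nucleoid extension rate relative to cell
#'   extension, in \[0, 1.5\]; 0 = arrested.
#' @param decondensation_target_ratio asymptotic nucleoid/cell length ratio
#'   in \[0, 1\] (NA keeps the cell's baseline ratio).
#' @param decondensation_tau_min time constant of the approach to the target.
#' @param growth_attenuation post-treatment growth-rate multiplier used by
#'   `arrest_mode = "gradual"` (scalar factor).
#' @param growth_decay_halflife_min if finite, the post-treatment growth rate
#'   additionally halves every this many minutes.
#' @param shrink_rate_per_min fractional length loss per minute after a
#'   shrink-mode arrest.
#' @param irregular_nucleoid jitter nucleoid segment boundaries frame to frame
#'   (DNA-class phenotype).
#' @param membrane_feature one of none, small_foci, large_blobs,
#'   septal_dimming, thick_septa.
#' @param membrane_feature_onset min after treatment (NA = at arrest).
#' @return an object of class `dbmi_preset` (a named list with the fields
#'   above).
#' @export
drug_response_preset <- function(name, moa_class, moa_subclass = "none",
                                 growth_arrest_onset = NA_real_,
                                 arrest_mode = "none",
                                 loss_after_arrest_min = NA_real_,
                                 nucleoid_loss_onset = NA_real_,
                                 nucleoid_loss_mode = "none",
                                 gradual_loss_fraction = 0,
                                 gradual_loss_floor = 1,
                                 gradual_loss_tau_min = 24,
                                 disintegration_lag = NA_real_,
                                 nucleoid_elongation_factor = 1,
                                 decondensation_target_ratio = NA_real_,
                                 decondensation_tau_min = NA_real_,
                                 growth_attenuation = 1,
                                 growth_decay_halflife_min = Inf,
                                 shrink_rate_per_min = 0,
                                 irregular_nucleoid = FALSE,
                                 membrane_feature = "none",
                                 membrane_feature_onset = NA_real_) {
  moa_class <- match.arg(moa_class, .moa_classes)
  moa_subclass <- match.arg(moa_subclass, .moa_subclasses)
  arrest_mode <- match.arg(arrest_mode, c("abrupt", "gradual", "shrink", "none"))
  nucleoid_loss_mode <- match.arg(nucleoid_loss_mode, c("sudden", "gradual", "none"))
  membrane_feature <- match.arg(membrane_feature, .membrane_features)

  if (all(is.na(nucleoid_loss_onset)) && is.na(loss_after_arrest_min) &&
      !all(is.na(disintegration_lag))) {
    stop("disintegration_lag requires a nucleoid loss event")
  }
  sub_of <- c(pore_former = "membrane", depolarizer = "membrane",
              transpeptidation_inhibitor = "wall", lipid_II_inhibitor = "wall",
              rnap_inhibitor = "rna", transcription_complex_inhibitor = "rna")
  if (moa_subclass != "none" && sub_of[[moa_subclass]] != moa_class) {
    stop(sprintf("moa_subclass '%s' is inconsistent with moa_class '%s'",
                 moa_subclass, moa_class))
  }
  if (moa_class == "control" &&
      (!all(is.na(c(growth_arrest_onset, nucleoid_loss_onset,
                    loss_after_arrest_min, disintegration_lag))) ||
       abs(nucleoid_elongation_factor - 1) > 0.05)) {
    stop("control preset must have no event onsets and elongation factor ~ 1")
  }
  stopifnot(nucleoid_elongation_factor >= 0, nucleoid_elongation_factor <= 1.5,
            is.na(decondensation_target_ratio) ||
              (decondensation_target_ratio >= 0 && decondensation_target_ratio <= 1))

  structure(list(
    name = name, moa_class = moa_class, moa_subclass = moa_subclass,
    growth_arrest_onset = growth_arrest_onset, arrest_mode = arrest_mode,
    loss_after_arrest_min = loss_after_arrest_min,
    nucleoid_loss_onset = nucleoid_loss_onset,
    nucleoid_loss_mode = nucleoid_loss_mode,
    gradual_loss_fraction = gradual_loss_fraction,
    gradual_loss_floor = gradual_loss_floor,
    gradual_loss_tau_min = gradual_loss_tau_min,
    disintegration_lag = disintegration_lag,
    nucleoid_elongation_factor = nucleoid_elongation_factor,
    decondensation_target_ratio = decondensation_target_ratio,
    decondensation_tau_min = decondensation_tau_min,
    growth_attenuation = growth_attenuation,
    growth_decay_halflife_min = growth_decay_halflife_min,
    shrink_rate_per_min = shrink_rate_per_min,
    irregular_nucleoid = irregular_nucleoid,
    membrane_feature = membrane_feature,
    membrane_feature_onset = membrane_feature_onset
  ), class = "dbmi_preset")
}

# Packaged response dynamics for the 14 antimicrobials + solvent control.
# Wall class: arrest sampled per cell on the frame grid within 15-30 min,
# sudden nucleoid loss 9 min (3 frames) after arrest, disintegration 6 or 9
# min after loss. Vancomycin's arrest is fixed at the ampicillin population
# mean + 20 min, rounded to the frame grid (42 min), with membrane blobs
# appearing well before arrest. Membrane class: simultaneous arrest and
# sudden loss at 6 min.
.preset_table <- function() {
  wall_common <- function(name, feature, feature_onset = NA_real_,
                          arrest = c(15, 30)) {
    drug_response_preset(name, "wall", "transpeptidation_inhibitor",
      growth_arrest_onset = arrest, arrest_mode = "abrupt",
      loss_after_arrest_min = 9, nucleoid_loss_mode = "sudden",
      disintegration_lag = c(6, 9),
      membrane_feature = feature, membrane_feature_onset = feature_onset)
  }
  list(
    ampicillin = wall_common("ampicillin", "septal_dimming"),
    penicillin_g = wall_common("penicillin_g", "septal_dimming"),
    vancomycin = {
      p <- wall_common("vancomycin", "large_blobs", feature_onset = 24,
                       arrest = 42)
      p$moa_subclass <- "lipid_II_inhibitor"
      p
    },
    cccp = drug_response_preset("cccp", "membrane", "depolarizer",
      growth_arrest_onset = 6, arrest_mode = "abrupt",
      nucleoid_loss_onset = 6, nucleoid_loss_mode = "sudden"),
    triclosan = drug_response_preset("triclosan", "membrane", "depolarizer",
      growth_arrest_onset = 6, arrest_mode = "abrupt",
      nucleoid_loss_onset = 6, nucleoid_loss_mode = "sudden",
      membrane_feature = "small_foci", membrane_feature_onset = 9),
    nisin = drug_response_preset("nisin", "membrane", "pore_former",
      growth_arrest_onset = 6, arrest_mode = "shrink",
      shrink_rate_per_min = 0.005,
      nucleoid_loss_onset = 6, nucleoid_loss_mode = "sudden",
      membrane_feature = "large_blobs", membrane_feature_onset = 30),
    chloramphenicol = drug_response_preset("chloramphenicol", "protein",
      arrest_mode = "gradual", growth_decay_halflife_min = 15,
      nucleoid_elongation_factor = 0,
      nucleoid_loss_mode = "gradual", gradual_loss_fraction = 0.5,
      gradual_loss_floor = 0.3, gradual_loss_tau_min = 24),
    fusidic_acid = drug_response_preset("fusidic_acid", "protein",
      arrest_mode = "gradual", growth_attenuation = 0.5,
      nucleoid_elongation_factor = 0),
    gentamicin = drug_response_preset("gentamicin", "protein",
      arrest_mode = "gradual", growth_decay_halflife_min = 20,
      nucleoid_elongation_factor = 0,
      nucleoid_loss_mode = "gradual", gradual_loss_fraction = 1,
      gradual_loss_floor = 0.3, gradual_loss_tau_min = 24),
    moxifloxacin = drug_response_preset("moxifloxacin", "dna",
      nucleoid_elongation_factor = 0.4, irregular_nucleoid = TRUE),
    nalidixic_acid = drug_response_preset("nalidixic_acid", "dna",
      nucleoid_elongation_factor = 0.4, irregular_nucleoid = TRUE),
    mitomycin_c = drug_response_preset("mitomycin_c", "dna",
      nucleoid_elongation_factor = 0.4, irregular_nucleoid = TRUE),
    rifampin = drug_response_preset("rifampin", "rna", "rnap_inhibitor",
      growth_arrest_onset = 0, arrest_mode = "abrupt",
      decondensation_target_ratio = 0.95, decondensation_tau_min = 5,
      nucleoid_loss_mode = "gradual", gradual_loss_fraction = 1,
      gradual_loss_floor = 0.7, gradual_loss_tau_min = 20),
    actinomycin_d = drug_response_preset("actinomycin_d", "rna",
      "transcription_complex_inhibitor",
      arrest_mode = "gradual", growth_attenuation = 0.4,
      decondensation_target_ratio = 0.7, decondensation_tau_min = 45),
    dmso_control = drug_response_preset("dmso_control", "control")
  )
}

#' List the packaged compound presets
#'
#' @return character vector of the 15 preset names (14 antimicrobials across
#'   the five main mechanism classes, plus the DMSO solvent control).
#' @export
list_presets <- function() names(.preset_table())

#' Look up a packaged drug-response preset
#'
#' @param name a compound identifier; see [list_presets()].
#' @return the [drug_response_preset()] object for that compound.
#' @examples
#' get_preset("cccp")$moa_class      # "membrane"
#' get_preset("ampicillin")$moa_subclass
#' @export
get_preset <- function(name) {
  tab <- .preset_table()
  if (length(name) != 1 || !name %in% names(tab)) {
    stop(sprintf("unknown preset '%s'; valid names: %s",
                 paste(name, collapse = ","),
                 paste(names(tab), collapse = ", ")))
  }
  tab[[name]]
}

#' Export the preset catalogue as a structured config file
#'
#' Writes every packaged preset, with keys exactly matching the
#' [drug_response_preset()] fields, to a YAML file.
#'
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
preset_catalogue <- function(path) {
  tab <- lapply(.preset_table(), function(p) lapply(unclass(p), function(x) {
    if (all(is.na(x))) NULL else x
  }))
  yaml::write_yaml(tab, path)
  invisible(path)
}

#' @export
print.dbmi_preset <- function(x, ...) {
  cat(sprintf("<dbmi_preset> %s  class=%s  subclass=%s\n",
              x$name, x$moa_class, x$moa_subclass))
  cat(sprintf("  arrest: %s (%s)  loss: %s (%s)  disintegration lag: %s\n",
              paste(x$growth_arrest_onset, collapse = "-"), x$arrest_mode,
              if (!is.na(x$loss_after_arrest_min))
                paste0("arrest+", x$loss_after_arrest_min)
              else paste(x$nucleoid_loss_onset, collapse = "-"),
              x$nucleoid_loss_mode,
              paste(x$disintegration_lag, collapse = "/")))
  cat(sprintf("  nucleoid elongation x%.2g  membrane feature: %s\n",
              x$nucleoid_elongation_factor, x$membrane_feature))
  invisible(x)
}
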