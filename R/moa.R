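# Three-level mechanism-of-action decision scheme.
#
# Level 1 separates cell-envelope stress (sudden loss of nucleoid staining)
# from non-envelope stress. Level 2 assigns the five target classes:
# simultaneous growth arrest and nucleoid loss -> membrane; arrest clearly
# before loss plus observed disintegration -> wall; among non-envelope
# classes the nucleoid/cell length ratio trend picks RNA (increasing), and a
# decreasing ratio is split by the nucleoid elongation state into protein
# (arrested) vs DNA (slowed). Level 3 resolves sub-classes within the
# membrane, wall and RNA classes; protein and DNA cannot be subdivided.

.ev <- function(criterion, observed, threshold, verdict) {
  data.frame(criterion = criterion,
             observed = as.character(observed),
             threshold = as.character(threshold),
             verdict = verdict, stringsAsFactors = FALSE)
}

.no_events <- function(ev) {
  is.na(ev$growth_arrest_min) && ev$nucleoid_loss_mode == "none" &&
    is.na(ev$disintegration_min) && ev$blobs == "none" && !ev$shrinkage &&
    ev$ratio_trend == "stable" &&
    ev$nucleoid_elongation_state %in% c("normal", "undetermined")
}

#' Classify one cell's mechanism of action from its events
#'
#' @param events a [cell_events()] list.
#' @param opts a [dbmi_options()] list (thresholds: simultaneity and
#'   precedence windows in frames, decondensation cut-off).
#' @param frame_interval_min acquisition interval, used to express the
#'   frame-based windows in minutes.
#' @return an object of class `dbmi_call` with `level1`
#'   (envelope/non_envelope/control), `level2` (membrane/wall/protein/dna/
#'   rna/control/unclassified), `level3` sub-class, and the per-criterion
#'   `evidence` data frame sufficient to recompute the call.
#' @export
classify_cell <- function(events, opts = dbmi_options(),
                          frame_interval_min = 3) {
  ev <- events
  evid <- list()
  simo <- opts$simultaneity_frames * frame_interval_min
  before <- opts$before_frames * frame_interval_min

  if (.no_events(ev)) {
    evid[[1]] <- .ev("any_event", "none", "any", "control")
    return(.call("control", "control", "none", do.call(rbind, evid)))
  }

  sudden <- ev$nucleoid_loss_mode == "sudden"
  evid[[length(evid) + 1]] <- .ev("nucleoid_loss_mode", ev$nucleoid_loss_mode,
                                  "sudden => envelope",
                                  if (sudden) "envelope" else "non_envelope")
  if (sudden) {
    dt_al <- ev$growth_arrest_min - ev$nucleoid_loss_min
    simult <- !is.na(dt_al) && abs(dt_al) <= simo
    evid[[length(evid) + 1]] <- .ev("arrest_loss_interval",
                                    ifelse(is.na(dt_al), "NA", dt_al),
                                    sprintf("|dt| <= %g min", simo),
                                    if (simult) "simultaneous" else "not simultaneous")
    if (simult) {
      lvl3 <- subclassify("membrane", ev, opts)
      return(.call("envelope", "membrane", lvl3$level3,
                   rbind(do.call(rbind, evid), lvl3$evidence)))
    }
    arrest_first <- !is.na(dt_al) && dt_al <= -before
    disint <- !is.na(ev$disintegration_min)
    evid[[length(evid) + 1]] <- .ev("arrest_before_loss",
                                    ifelse(is.na(dt_al), "NA", dt_al),
                                    sprintf("dt <= -%g min", before),
                                    if (arrest_first) "yes" else "no")
    evid[[length(evid) + 1]] <- .ev("disintegration_observed",
                                    ifelse(disint, ev$disintegration_min, "none"),
                                    "required for wall",
                                    if (disint) "yes" else "no")
    if (arrest_first && disint) {
      lvl3 <- subclassify("wall", ev, opts)
      return(.call("envelope", "wall", lvl3$level3,
                   rbind(do.call(rbind, evid), lvl3$evidence)))
    }
    evid[[length(evid) + 1]] <- .ev("envelope_conflict",
                                    "sudden loss without membrane or wall signature",
                                    "", "unclassified")
    return(.call("envelope", "unclassified", "none", do.call(rbind, evid)))
  }

  evid[[length(evid) + 1]] <- .ev("ratio_trend", ev$ratio_trend,
                                  "increasing => rna", ev$ratio_trend)
  if (ev$ratio_trend == "increasing") {
    lvl3 <- subclassify("rna", ev, opts)
    return(.call("non_envelope", "rna", lvl3$level3,
                 rbind(do.call(rbind, evid), lvl3$evidence)))
  }
  if (ev$ratio_trend == "decreasing") {
    st <- ev$nucleoid_elongation_state
    evid[[length(evid) + 1]] <- .ev("nucleoid_elongation_state", st,
                                    "arrested => protein; slowed => dna", st)
    if (st == "arrested") {
      return(.call("non_envelope", "protein", "none", do.call(rbind, evid)))
    }
    if (st == "slowed") {
      return(.call("non_envelope", "dna", "none", do.call(rbind, evid)))
    }
  }
  evid[[length(evid) + 1]] <- .ev("non_envelope_pattern",
                                  sprintf("trend=%s, elongation=%s",
                                          ev$ratio_trend,
                                          ev$nucleoid_elongation_state),
                                  "", "unclassified")
  .call("non_envelope", "unclassified", "none", do.call(rbind, evid))
}

.call <- function(level1, level2, level3, evidence, votes = NULL,
                  vote_fractions = NULL, n_cells = 1L, cell_calls = NULL) {
  structure(list(level1 = level1, level2 = level2, level3 = level3,
                 evidence = evidence, votes = votes,
                 vote_fractions = vote_fractions, n_cells = n_cells,
                 cell_calls = cell_calls),
            class = "dbmi_call")
}

#' Sub-classify within the membrane, wall or RNA class
#'
#' Membrane: cell shrinkage plus large membrane blobs indicate pore
#' formation; little or no membrane aggregation indicates depolarisation.
#' Wall: large blobs (or thickened septa) before growth arrest indicate a
#' lipid II synthesis block; an unremarkable membrane before arrest
#' indicates a transpeptidation (cross-linking) block. RNA: essentially
#' complete nucleoid decondensation indicates RNA-polymerase inhibition;
#' partial decondensation indicates a transcription-complex block. The
#' protein and DNA classes are not subdivided.
#'
#' @param level2 level-2 class.
#' @param events a [cell_events()] list.
#' @param opts a [dbmi_options()] list.
#' @return list with `level3` and `evidence`.
#' @export
subclassify <- function(level2, events, opts = dbmi_options()) {
  ev <- events
  if (level2 == "membrane") {
    pore <- ev$shrinkage && ev$blobs == "large_blobs"
    return(list(level3 = if (pore) "pore_former" else "depolarizer",
                evidence = .ev("shrinkage_and_large_blobs",
                               sprintf("shrinkage=%s, blobs=%s",
                                       ev$shrinkage, ev$blobs),
                               "both => pore_former",
                               if (pore) "pore_former" else "depolarizer")))
  }
  if (level2 == "wall") {
    early <- !is.na(ev$blob_onset_min) && !is.na(ev$growth_arrest_min) &&
      ev$blobs %in% c("large_blobs") && ev$blob_onset_min < ev$growth_arrest_min
    return(list(level3 = if (early) "lipid_II_inhibitor" else "transpeptidation_inhibitor",
                evidence = .ev("blobs_before_arrest",
                               sprintf("blobs=%s at %s min, arrest %s min",
                                       ev$blobs, ev$blob_onset_min,
                                       ev$growth_arrest_min),
                               "large blobs before arrest => lipid_II",
                               if (early) "lipid_II_inhibitor"
                               else "transpeptidation_inhibitor")))
  }
  if (level2 == "rna") {
    full <- !is.na(ev$decondensation_extent) &&
      ev$decondensation_extent >= opts$decondensation_cutoff
    return(list(level3 = if (full) "rnap_inhibitor" else "transcription_complex_inhibitor",
                evidence = .ev("decondensation_extent",
                               round(ev$decondensation_extent, 3),
                               sprintf(">= %g => rnap_inhibitor",
                                       opts$decondensation_cutoff),
                               if (full) "rnap_inhibitor"
                               else "transcription_complex_inhibitor")))
  }
  list(level3 = "none",
       evidence = .ev("subclass", level2,
                      "only membrane/wall/rna have sub-classes", "none"))
}

#' Population-level mechanism call from per-cell calls
#'
#' Majority vote over per-cell level-2 calls (unclassifiable cells abstain).
#' A wall call additionally requires observed disintegration in at least
#' `wall_disintegration_frac` of the cells (disintegration is the wall
#' class's conserved trait, but a single-cell observation could be noise).
#' Ties give `unclassified`. Level 3 is the majority among the cells voting
#' for the winning class.
#'
#' @param cell_calls list of [classify_cell()] results.
#' @param cell_events_list the corresponding [cell_events()] lists (used for
#'   the population disintegration fraction).
#' @param opts a [dbmi_options()] list (`min_cells`,
#'   `wall_disintegration_frac`).
#' @return a `dbmi_call` with vote counts and fractions.
#' @export
classify_compound <- function(cell_calls, cell_events_list = NULL,
                              opts = dbmi_options()) {
  n <- length(cell_calls)
  if (n < opts$min_cells) {
    stop(sprintf("%d classified cells given but at least %d are required",
                 n, opts$min_cells))
  }
  l2 <- vapply(cell_calls, function(cc) cc$level2, character(1))
  voting <- l2[l2 != "unclassified"]
  votes <- table(factor(voting, levels = c("membrane", "wall", "protein",
                                           "dna", "rna", "control")))
  fr <- as.numeric(votes) / max(sum(votes), 1)
  names(fr) <- names(votes)
  evid <- .ev("level2_votes", paste(sprintf("%s=%d", names(votes), votes),
                                    collapse = ", "),
              "majority", "")
  if (!length(voting)) {
    return(.call("non_envelope", "unclassified", "none", evid, votes, fr, n,
                 cell_calls))
  }
  top <- which(votes == max(votes))
  if (length(top) > 1) {
    evid$verdict <- "tie"
    return(.call("non_envelope", "unclassified", "none", evid, votes, fr, n,
                 cell_calls))
  }
  winner <- names(votes)[top]
  evid$verdict <- winner
  if (winner == "wall") {
    dis_frac <- if (is.null(cell_events_list)) NA_real_ else {
      mean(vapply(cell_events_list,
                  function(e) !is.na(e$disintegration_min), logical(1)))
    }
    ok <- !is.na(dis_frac) && dis_frac >= opts$wall_disintegration_frac
    evid <- rbind(evid, .ev("population_disintegration_fraction",
                            round(dis_frac, 3),
                            sprintf(">= %g", opts$wall_disintegration_frac),
                            if (ok) "wall confirmed" else "wall rejected"))
    if (!ok) {
      return(.call("envelope", "unclassified", "none", evid, votes, fr, n,
                   cell_calls))
    }
  }
  l3_pool <- vapply(cell_calls[l2 == winner], function(cc) cc$level3,
                    character(1))
  l3 <- if (length(l3_pool)) names(sort(table(l3_pool), decreasing = TRUE))[1]
        else "none"
  level1 <- switch(winner, membrane = , wall = "envelope",
                   control = "control", "non_envelope")
  .call(level1, winner, l3, evid, votes, fr, n, cell_calls)
}

#' @export
print.dbmi_call <- function(x, ...) {
  cat(sprintf("<dbmi_call> level1=%s  level2=%s  level3=%s  (n=%d)\n",
              x$level1, x$level2, x$level3, x$n_cells))
  if (!is.null(x$votes)) {
    v <- x$votes[x$votes > 0]
    if (length(v)) cat("  votes:", paste(sprintf("%s=%d", names(v), v),
                                         collapse = ", "), "\n")
  }
  invisible(x)
}
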