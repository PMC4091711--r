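#' Classify a channel's pole preference
#'
#' Population-level rule: in dividing cells (length at or above the
#' dividing threshold), a locus whose foci sit closer to the septum
#' (midcell) than to the poles lies near the future new pole; a locus
#' whose foci hug the poles lies near the old pole.  Each qualifying
#' cell votes (mean per-focus septum distance vs mean pole distance;
#' exact ties vote old-pole) and the majority calls the preference.
#'
#' @param ds a \code{\link{strain_dataset}}.
#' @param channel channel name.
#' @param dividing_length_threshold minimum length (um) of a dividing
#'   cell; default the 90th percentile of binning lengths.
#' @param min_cells minimum number of qualifying dividing cells (1 or 2
#'   foci); below it the preference is ambiguous, with a warning.
#' @param margin_threshold minimum |vote fraction - 0.5| for a
#'   non-ambiguous call.
#' @return object of class \code{pole_preference}: fields
#'   \code{channel}, \code{preference} (\code{"old_pole"},
#'   \code{"new_pole"} or \code{"ambiguous"}), \code{margin},
#'   \code{n_cells}, \code{dividing_length_threshold}.
#' @export
classify_pole_preference <- function(ds, channel,
                                     dividing_length_threshold = NULL,
                                     min_cells = 20,
                                     margin_threshold = 0.1) {
  if (is.null(dividing_length_threshold))
    dividing_length_threshold <- stats::quantile(binning_length(ds), 0.9,
                                                 names = FALSE, type = 7)
  cnt <- focus_count(ds, channel)
  div <- binning_length(ds) >= dividing_length_threshold &
    cnt %in% c(1L, 2L)
  ft <- focus_table(ds, channel)
  ft <- ft[ft$cell_id %in% ds$cells$cell_id[div], , drop = FALSE]
  d_sept <- abs(ft$position_um - ft$length_um / 2)
  d_pole <- pmin(ft$position_um, ft$length_um - ft$position_um)
  ms <- tapply(d_sept, ft$cell_id, mean)
  mp <- tapply(d_pole, ft$cell_id, mean)
  # vote: new pole when strictly septum-proximal; ties go old-pole
  votes_new <- ms < mp
  n <- length(votes_new)
  out <- list(channel = channel, preference = "ambiguous", margin = 0,
              n_cells = n,
              dividing_length_threshold = dividing_length_threshold)
  if (n < min_cells) {
    warning(sprintf("channel %s: only %d dividing cells (need %d); %s",
                    channel, n, min_cells, "preference ambiguous"))
    return(structure(out, class = "pole_preference"))
  }
  frac_new <- mean(votes_new)
  out$margin <- abs(frac_new - 0.5)
  if (out$margin >= margin_threshold)
    out$preference <- if (frac_new > 0.5) "new_pole" else "old_pole"
  structure(out, class = "pole_preference")
}

#' @export
print.pole_preference <- function(x, ...) {
  cat(sprintf("<pole_preference> %s: %s (margin %.2f, n=%d)\n",
              x$channel, x$preference, x$margin, x$n_cells))
  invisible(x)
}

#' Orient cells along the new-pole to old-pole axis
#'
#' Per-cell asymmetry score
#' \eqn{S = \sum_c w_c\, s_c\, (\bar{x}_c/L - 1/2)} over channels with a
#' non-ambiguous pole preference and 1 or 2 foci, where \eqn{s_c = +1}
#' for old-pole channels, \eqn{-1} for new-pole channels and
#' \eqn{w_c} is the preference margin.  The stored axis is flipped when
#' \eqn{S < 0} so that relative position 0 is the new pole; cells with
#' \eqn{|S| < } \code{ambiguity_tolerance}\eqn{\times \sum_c w_c} are
#' marked ambiguous (and \eqn{S = 0} is never flipped).
#'
#' @param ds a \code{\link{strain_dataset}}.
#' @param preferences list of \code{pole_preference} objects (defaults
#'   to classifying every channel).
#' @param ambiguity_tolerance relative-score threshold below which a
#'   cell is ambiguous.
#' @return the dataset with \code{orientation} and \code{polarity_flip}
#'   filled in.  If every preference is ambiguous the dataset is
#'   returned unoriented with attribute \code{orientation_failed}.
#' @export
orient_cells <- function(ds, preferences = NULL,
                         ambiguity_tolerance = 0.1) {
  if (is.null(preferences))
    preferences <- lapply(ds_channels(ds), function(ch)
      classify_pole_preference(ds, ch))
  usable <- Filter(function(p) p$preference != "ambiguous", preferences)
  if (!length(usable)) {
    ds$cells$orientation <- "unoriented"
    ds$cells$polarity_flip <- NA
    attr(ds, "orientation_failed") <- TRUE
    warning("all channel preferences ambiguous; dataset left unoriented")
    return(ds)
  }
  n <- nrow(ds$cells)
  score <- numeric(n)
  wsum <- numeric(n)
  for (p in usable) {
    cnt <- focus_count(ds, p$channel)
    ft <- focus_table(ds, p$channel)
    mrel <- tapply(ft$rel, factor(ft$cell_id, levels = ds$cells$cell_id),
                   mean)
    sgn <- if (p$preference == "old_pole") 1 else -1
    use <- cnt %in% c(1L, 2L)
    score[use] <- score[use] +
      p$margin * sgn * (mrel[use] - 0.5)
    wsum[use] <- wsum[use] + p$margin
  }
  ambiguous <- wsum == 0 | abs(score) < ambiguity_tolerance * wsum
  ds$cells$orientation <- ifelse(ambiguous, "ambiguous", "oriented")
  ds$cells$polarity_flip <- ifelse(ambiguous, NA, score < 0)
  ds
}

#' Rescue ambiguous orientations against profile templates
#'
#' Template pass: provisional size-binned profiles are built from the
#' non-ambiguous cells; each ambiguous cell is then assigned the
#' orientation (as-stored or flipped) that minimises the summed absolute
#' deviation of its foci from the profile medians of its length
#' interval, provided the improvement exceeds \code{margin} (otherwise
#' it stays ambiguous; exact ties always do).  Iterates to a fixed
#' point.
#'
#' @param ds an oriented \code{\link{strain_dataset}} (output of
#'   \code{\link{orient_cells}}).
#' @param channels channels used for matching; default all.
#' @param max_iter maximum template iterations.
#' @param margin minimum summed-deviation improvement (relative units)
#'   required to assign an orientation.
#' @param asym_min minimum template asymmetry for a channel/window to be
#'   used: dominant-one windows need a median at least this far from
#'   midcell, dominant-two windows a sister pair at least this far from
#'   mirror symmetry.  A mirror-symmetric template carries no
#'   orientation information, only noise.
#' @return the dataset with some ambiguous cells re-oriented.
#' @export
refine_orientation <- function(ds, channels = NULL, max_iter = 5,
                               margin = 0.15, asym_min = 0.1) {
  if (is.null(channels)) channels <- ds_channels(ds)
  for (it in seq_len(max_iter)) {
    amb <- which(ds$cells$orientation == "ambiguous")
    if (!length(amb)) break
    profiles <- lapply(channels, function(ch)
      position_profile(ds, ch))
    names(profiles) <- channels
    binL <- binning_length(ds)
    changed <- FALSE
    for (i in amb) {
      dev <- c(asis = 0, flip = 0)
      nterm <- 0L
      for (ch in channels) {
        prof <- profiles[[ch]]
        if (!nrow(prof)) next
        j <- which.min(abs(prof$center - bin_index(binL[i])))
        if (!length(j) || is.na(prof$dominant_type[j])) next
        f <- ds$foci[ds$foci$cell_id == ds$cells$cell_id[i] &
                       ds$foci$channel == ch, , drop = FALSE]
        rel <- sort(f$position_um / ds$cells$length_um[i])
        if (length(rel) == 1L && prof$dominant_type[j] == "one" &&
            abs(prof$med[j] - 0.5) > asym_min) {
          m <- prof$med[j]
          dev["asis"] <- dev["asis"] + abs(rel - m)
          dev["flip"] <- dev["flip"] + abs((1 - rel) - m)
          nterm <- nterm + 1L
        } else if (length(rel) == 2L && prof$dominant_type[j] == "two" &&
                   abs(prof$lo_med[j] + prof$up_med[j] - 1) > asym_min) {
          m <- c(prof$lo_med[j], prof$up_med[j])
          dev["asis"] <- dev["asis"] + sum(abs(rel - m))
          dev["flip"] <- dev["flip"] + sum(abs(sort(1 - rel) - m))
          nterm <- nterm + 1L
        }
      }
      if (nterm == 0L) next
      if (abs(dev["asis"] - dev["flip"]) <= margin) next
      ds$cells$orientation[i] <- "oriented"
      ds$cells$polarity_flip[i] <- dev["flip"] < dev["asis"]
      changed <- TRUE
    }
    if (!changed) break
  }
  ds
}

#' Compare inferred orientations with simulation ground truth
#'
#' @param ds an oriented dataset produced from a simulation.
#' @param truth the matching \code{ground_truth}.
#' @return list with \code{n_oriented}, \code{n_ambiguous},
#'   \code{accuracy} (fraction of non-ambiguous cells whose inferred
#'   flip matches the true one) and \code{ambiguous_fraction}.
#' @export
orientation_accuracy <- function(ds, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  i <- match(ds$cells$cell_id, truth$cells$cell_id)
  ok <- ds$cells$orientation == "oriented"
  acc <- if (any(ok))
    mean(ds$cells$polarity_flip[ok] == truth$cells$flipped[i][ok])
  else NA_real_
  list(n_oriented = sum(ok), n_ambiguous = sum(!ok),
       accuracy = acc, ambiguous_fraction = mean(!ok))
}
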