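#' Compute a cross-strain cell-length alignment offset
#'
#' Two strains imaged separately can have slightly different length
#' distributions; their choreographies are compared after shifting the
#' target strain's length axis so that a shared anchor event falls in
#' the same length interval.  Anchors are either the first interval
#' where the duplication frequency of a common channel reaches a
#' threshold, or the first interval where a (dominant single-focus)
#' channel's median position settles at midcell.
#'
#' @param ref_ds,target_ds \code{\link{strain_dataset}}s sharing the
#'   anchor channel.
#' @param anchor list: \code{channel}; \code{type} =
#'   \code{"duplication_threshold"} (with \code{threshold}, default 0.5)
#'   or \code{"midcell_recruitment"} (with \code{delta}, default 0.1,
#'   and \code{persist}, default 2 consecutive intervals).
#' @param interval_width_um,window_um,min_cells windowing parameters
#'   (see \code{\link{duplication_frequency}}).
#' @return object of class \code{alignment_offset}: \code{ref},
#'   \code{target}, \code{anchor}, \code{offset_um} (a multiple of the
#'   interval width, to be added to target lengths).
#' @export
compute_offset <- function(ref_ds, target_ds, anchor,
                           interval_width_um = 0.1, window_um = 0.3,
                           min_cells = 10) {
  stopifnot(is.list(anchor), !is.null(anchor$channel),
            !is.null(anchor$type))
  a_ref <- anchor_interval(ref_ds, anchor, interval_width_um,
                           window_um, min_cells)
  a_tgt <- anchor_interval(target_ds, anchor, interval_width_um,
                           window_um, min_cells)
  if (is.na(a_ref) || is.na(a_tgt))
    stop(sprintf("anchor '%s' on channel %s not reached in %s",
                 anchor$type, anchor$channel,
                 if (is.na(a_ref)) ref_ds$strain_id
                 else target_ds$strain_id))
  off <- round((a_ref - a_tgt) / interval_width_um) * interval_width_um
  structure(list(ref = ref_ds$strain_id, target = target_ds$strain_id,
                 anchor = anchor, offset_um = off),
            class = "alignment_offset")
}

anchor_interval <- function(ds, anchor, interval_width_um, window_um,
                            min_cells) {
  if (!anchor$channel %in% ds_channels(ds))
    stop("anchor channel absent from ", ds$strain_id)
  if (anchor$type == "duplication_threshold") {
    thr <- if (is.null(anchor$threshold)) 0.5 else anchor$threshold
    dup <- duplication_frequency(ds, anchor$channel, interval_width_um,
                                 window_um, min_cells)
    first_crossing(dup, thr)
  } else if (anchor$type == "midcell_recruitment") {
    delta <- if (is.null(anchor$delta)) 0.1 else anchor$delta
    persist <- if (is.null(anchor$persist)) 2L else anchor$persist
    prof <- position_profile(ds, anchor$channel, interval_width_um,
                             window_um, min_cells)
    inband <- !is.na(prof$dominant_type) & prof$dominant_type == "one" &
      abs(prof$med - 0.5) <= delta
    runs <- rle(inband)
    ends <- cumsum(runs$lengths)
    hit <- which(runs$values & runs$lengths >= persist)
    if (!length(hit)) NA_real_
    else prof$center[ends[hit[1]] - runs$lengths[hit[1]] + 1L]
  } else stop("unknown anchor type: ", anchor$type)
}

#' @export
print.alignment_offset <- function(x, ...) {
  cat(sprintf("<alignment_offset> %s -> %s: %+.1f um (%s on %s)\n",
              x$target, x$ref, x$offset_um, x$anchor$type,
              x$anchor$channel))
  invisible(x)
}

#' Apply an alignment offset to a dataset
#'
#' Adds the offset to the dataset's length-binning axis.  Focus
#' coordinates and measured lengths are untouched: relative positions
#' remain ratios against the measured length; the offset only shifts
#' cells between length intervals (it is a population-comparison
#' device, not a cell-geometry claim).
#'
#' @param ds a \code{\link{strain_dataset}}.
#' @param offset an \code{alignment_offset} or a numeric offset in um.
#' @return the dataset with its cumulative \code{length_offset_um}
#'   updated.
#' @export
apply_offset <- function(ds, offset) {
  off <- if (inherits(offset, "alignment_offset")) offset$offset_um
         else as.numeric(offset)
  new_off <- ds$length_offset_um + off
  if (nrow(ds$cells) && any(ds$cells$length_um + new_off <= 0))
    stop("offset would produce non-positive binning lengths")
  ds$length_offset_um <- new_off
  ds
}
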