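#' Construct a strain dataset
#'
#' The central container of the pipeline: a collection of segmented cells
#' with per-channel axial focus positions, plus the mapping from
#' fluorescent channels to genomic loci.  Axial positions are stored in
#' micrometres from an arbitrary reference pole; orientation (which pole
#' is the new pole) is a separate, recorded transformation applied by
#' \code{\link{orient_cells}}.
#'
#' @param strain_id identifier.
#' @param cells data.frame with columns \code{cell_id}, \code{length_um},
#'   and optionally \code{orientation} (\code{"unoriented"},
#'   \code{"oriented"} or \code{"ambiguous"}) and \code{polarity_flip}
#'   (logical; \code{TRUE} means the stored axis must be reversed so that
#'   relative position 0 is the new pole).
#' @param foci data.frame with columns \code{cell_id}, \code{channel},
#'   \code{position_um} (one row per focus).
#' @param channel_locus_map named list mapping channel names to
#'   \code{\link{locus}} objects (may be incomplete; flagged by
#'   \code{\link{validate_dataset}}).
#' @param length_offset_um realignment shift already applied to this
#'   dataset's length axis (see \code{\link{apply_offset}}).
#' @param scenario free-text metadata.
#' @return Object of class \code{strain_dataset}.
#' @export
strain_dataset <- function(strain_id, cells, foci,
                           channel_locus_map = list(),
                           length_offset_um = 0, scenario = "") {
  stopifnot(is.data.frame(cells),
            all(c("cell_id", "length_um") %in% names(cells)))
  if (is.null(cells$orientation))
    cells$orientation <- rep("unoriented", nrow(cells))
  if (is.null(cells$polarity_flip))
    cells$polarity_flip <- rep(NA, nrow(cells))
  if (nrow(cells) && any(!is.finite(cells$length_um) | cells$length_um <= 0))
    stop("all cell lengths must be positive and finite")
  if (is.null(foci) || !nrow(foci)) {
    foci <- data.frame(cell_id = character(), channel = character(),
                       position_um = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("cell_id", "channel", "position_um") %in% names(foci)))
  if (nrow(foci)) {
    len <- cells$length_um[match(foci$cell_id, cells$cell_id)]
    if (any(is.na(len)))
      stop("foci reference unknown cell_id")
    if (any(foci$position_um < 0 | foci$position_um > len))
      stop("focus positions must lie within [0, cell length]")
  }
  rownames(cells) <- NULL
  rownames(foci) <- NULL
  structure(list(strain_id = strain_id,
                 cells = cells, foci = foci,
                 channel_locus_map = channel_locus_map,
                 length_offset_um = length_offset_um,
                 scenario = scenario),
            class = "strain_dataset")
}

#' @export
print.strain_dataset <- function(x, ...) {
  cat(sprintf("<strain_dataset> %s: %d cells, %d foci, channels: %s\n",
              x$strain_id, nrow(x$cells), nrow(x$foci),
              paste(ds_channels(x), collapse = ", ")))
  if (x$length_offset_um != 0)
    cat(sprintf("  length offset applied: %+.2f um\n", x$length_offset_um))
  invisible(x)
}

#' Channels present in a dataset
#' @param ds a \code{strain_dataset}.
#' @return character vector of channel names.
#' @export
ds_channels <- function(ds) {
  union(unique(ds$foci$channel), names(ds$channel_locus_map))
}

#' Cell length used for length binning
#'
#' Measured length plus the realignment offset.  Relative positions are
#' always ratios against the measured length; the offset only moves cells
#' between length intervals for cross-strain comparison.
#'
#' @param ds a \code{strain_dataset}.
#' @return numeric vector, one value per cell.
#' @export
binning_length <- function(ds) ds$cells$length_um + ds$length_offset_um

#' Per-cell focus count in one channel
#'
#' @param ds a \code{strain_dataset}.
#' @param channel channel name.
#' @return integer vector aligned with \code{ds$cells}; cells without a
#'   focus in the channel get 0.
#' @export
focus_count <- function(ds, channel) {
  f <- ds$foci[ds$foci$channel == channel, , drop = FALSE]
  tab <- table(factor(f$cell_id, levels = ds$cells$cell_id))
  as.integer(tab)
}

# long per-focus table with lengths, relative and (if available) oriented
# relative positions; rel_oriented is NA for unoriented/ambiguous cells
focus_table <- function(ds, channel) {
  f <- ds$foci[ds$foci$channel == channel, , drop = FALSE]
  i <- match(f$cell_id, ds$cells$cell_id)
  L <- ds$cells$length_um[i]
  rel <- f$position_um / L
  flip <- ds$cells$polarity_flip[i]
  oriented <- ds$cells$orientation[i] == "oriented" & !is.na(flip)
  rel_or <- ifelse(oriented, ifelse(flip, 1 - rel, rel), NA_real_)
  data.frame(cell_id = f$cell_id, position_um = f$position_um,
             length_um = L, bin_length_um = L + ds$length_offset_um,
             rel = rel, rel_oriented = rel_or,
             oriented = oriented, stringsAsFactors = FALSE)
}

#' Reverse the stored axis of every cell
#'
#' Utility for invariance checks: each focus at \code{x} becomes
#' \code{L - x}.  Orientation state is reset to unoriented.
#'
#' @param ds a \code{strain_dataset}.
#' @return the flipped \code{strain_dataset}.
#' @export
flip_dataset <- function(ds) {
  if (nrow(ds$foci)) {
    L <- ds$cells$length_um[match(ds$foci$cell_id, ds$cells$cell_id)]
    ds$foci$position_um <- L - ds$foci$position_um
  }
  ds$cells$orientation <- "unoriented"
  ds$cells$polarity_flip <- NA
  ds
}

#' Validate a strain dataset
#'
#' Report-only: counts cells, tabulates per-channel focus counts
#' (0 / 1 / 2 / many), reports the length range and flags channels that
#' appear in cells but are absent from the channel-to-locus map.
#'
#' @param ds a \code{strain_dataset}.
#' @return list with elements \code{n_cells}, \code{length_range_um},
#'   \code{focus_histograms} (per channel, named counts), and
#'   \code{unmapped_channels}.
#' @export
validate_dataset <- function(ds) {
  chans <- sort(unique(ds$foci$channel))
  hist <- lapply(chans, function(ch) {
    n <- focus_count(ds, ch)
    cls <- ifelse(n > 2, "many", as.character(n))
    table(factor(cls, levels = c("0", "1", "2", "many")))
  })
  names(hist) <- chans
  list(n_cells = nrow(ds$cells),
       length_range_um = if (nrow(ds$cells)) range(ds$cells$length_um)
                         else c(NA_real_, NA_real_),
       focus_histograms = hist,
       unmapped_channels = setdiff(chans, names(ds$channel_locus_map)))
}
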