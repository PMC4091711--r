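#' Length-interval index of a cell
#'
#' Cells are classified by length into half-open intervals
#' \code{[k*w, (k+1)*w)} of width \code{w} (default 0.1 um), labelled by
#' their lower edge.
#'
#' @param length_um cell length(s) in micrometres.
#' @param interval_width_um interval width.
#' @return numeric vector of interval labels (lower edges).
#' @export
bin_index <- function(length_um, interval_width_um = 0.1) {
  stopifnot(all(length_um > 0))
  floor(length_um / interval_width_um + 1e-9) * interval_width_um
}

# window centers spanning the binning lengths of a dataset, as exact
# integer multiples of the interval width
window_centers <- function(binL, interval_width_um = 0.1) {
  if (!length(binL)) return(numeric())
  lo <- floor(min(binL) / interval_width_um + 1e-9)
  hi <- floor(max(binL) / interval_width_um + 1e-9)
  (lo:hi) * interval_width_um
}

# logical window membership: binning length in [c - w/2, c + w/2)
in_window <- function(binL, center, window_um) {
  binL >= center - window_um / 2 & binL < center + window_um / 2
}

#' Sliding-window duplication frequency
#'
#' For every 0.1 um length interval, pools cells whose (realigned)
#' length falls in the surrounding 0.3 um window and reports the
#' fraction of 2-focus cells among 1- and 2-focus cells.
#' Orientation-free: invariant under axis flips.  Windows with fewer
#' than \code{min_cells} scoring cells are masked (\code{NA}).
#'
#' @param ds a \code{\link{strain_dataset}}.
#' @param channel channel name.
#' @param interval_width_um,window_um interval and sliding-window width.
#' @param min_cells minimum 1+2-focus cells per window.
#' @return data.frame with columns \code{center}, \code{n_1focus},
#'   \code{n_2focus}, \code{fraction}.
#' @export
duplication_frequency <- function(ds, channel, interval_width_um = 0.1,
                                  window_um = 0.3, min_cells = 10) {
  if (!channel %in% ds_channels(ds)) stop("channel absent: ", channel)
  cnt <- focus_count(ds, channel)
  binL <- binning_length(ds)
  centers <- window_centers(binL, interval_width_um)
  n1 <- n2 <- integer(length(centers))
  for (i in seq_along(centers)) {
    sel <- in_window(binL, centers[i], window_um)
    n1[i] <- sum(cnt[sel] == 1L)
    n2[i] <- sum(cnt[sel] == 2L)
  }
  frac <- ifelse(n1 + n2 >= min_cells, n2 / (n1 + n2), NA_real_)
  data.frame(center = centers, n_1focus = n1, n_2focus = n2,
             fraction = frac)
}

#' Size-binned position profile of a locus
#'
#' The trajectory-reconstruction statistic: per sliding window, the
#' duplication frequency decides the dominant cell type (two-focus when
#' the fraction is >= \code{dominant_threshold}); the median and
#' 25th/75th percentiles of the oriented relative positions (0 = new
#' pole) are then reported for that type -- one set for single-focus
#' windows, one set per sister rank (lower/upper, ordered within each
#' cell) for two-focus windows.  Only oriented cells contribute;
#' ambiguous and unoriented cells are excluded.
#'
#' @inheritParams duplication_frequency
#' @param dominant_threshold two-focus dominance threshold.
#' @return data.frame of class \code{size_binned_profile}: columns
#'   \code{center}, \code{n_cells}, \code{n_1focus}, \code{n_2focus},
#'   \code{duplication_fraction}, \code{dominant_type}, \code{med},
#'   \code{p25}, \code{p75} (dominant-one windows) and \code{lo_med},
#'   \code{lo_p25}, \code{lo_p75}, \code{up_med}, \code{up_p25},
#'   \code{up_p75} (dominant-two windows).
#' @export
position_profile <- function(ds, channel, interval_width_um = 0.1,
                             window_um = 0.3, min_cells = 10,
                             dominant_threshold = 0.5) {
  if (!channel %in% ds_channels(ds)) stop("channel absent: ", channel)
  ok <- ds$cells$orientation == "oriented"
  if (!any(ok)) {
    out <- empty_profile()
    attr(out, "no_oriented_cells") <- TRUE
    return(out)
  }
  sub <- ds
  sub$cells <- ds$cells[ok, , drop = FALSE]
  sub$foci <- ds$foci[ds$foci$cell_id %in% sub$cells$cell_id, ,
                      drop = FALSE]
  cnt <- focus_count(sub, channel)
  binL <- binning_length(sub)
  ft <- focus_table(sub, channel)
  # oriented relative positions indexed per cell
  rel_by_cell <- split(ft$rel_oriented,
                       factor(ft$cell_id, levels = sub$cells$cell_id))
  centers <- window_centers(binL, interval_width_um)
  rows <- vector("list", length(centers))
  q3 <- function(x) stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE,
                                    type = 7)
  for (i in seq_along(centers)) {
    sel <- which(in_window(binL, centers[i], window_um))
    n1 <- sum(cnt[sel] == 1L); n2 <- sum(cnt[sel] == 2L)
    r <- list(center = centers[i], n_cells = length(sel),
              n_1focus = n1, n_2focus = n2,
              duplication_fraction = NA_real_,
              dominant_type = NA_character_,
              med = NA_real_, p25 = NA_real_, p75 = NA_real_,
              lo_med = NA_real_, lo_p25 = NA_real_, lo_p75 = NA_real_,
              up_med = NA_real_, up_p25 = NA_real_, up_p75 = NA_real_)
    if (n1 + n2 >= min_cells) {
      r$duplication_fraction <- n2 / (n1 + n2)
      if (r$duplication_fraction >= dominant_threshold) {
        r$dominant_type <- "two"
        cells2 <- sel[cnt[sel] == 2L]
        lo <- vapply(rel_by_cell[cells2], min, numeric(1))
        up <- vapply(rel_by_cell[cells2], max, numeric(1))
        r[c("lo_med", "lo_p25", "lo_p75")] <- as.list(q3(lo))
        r[c("up_med", "up_p25", "up_p75")] <- as.list(q3(up))
      } else {
        r$dominant_type <- "one"
        cells1 <- sel[cnt[sel] == 1L]
        x <- unlist(rel_by_cell[cells1], use.names = FALSE)
        r[c("med", "p25", "p75")] <- as.list(q3(x))
      }
    }
    rows[[i]] <- as.data.frame(r, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("size_binned_profile", "data.frame")
  attr(out, "channel") <- channel
  attr(out, "interval_width_um") <- interval_width_um
  attr(out, "window_um") <- window_um
  out
}

empty_profile <- function() {
  out <- data.frame(center = numeric(), n_cells = integer(),
                    n_1focus = integer(), n_2focus = integer(),
                    duplication_fraction = numeric(),
                    dominant_type = character(),
                    med = numeric(), p25 = numeric(), p75 = numeric(),
                    lo_med = numeric(), lo_p25 = numeric(),
                    lo_p75 = numeric(), up_med = numeric(),
                    up_p25 = numeric(), up_p75 = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("size_binned_profile", "data.frame")
  out
}

#' First interval crossing a duplication threshold
#'
#' Smallest window center whose (unmasked) duplication fraction reaches
#' the threshold.
#'
#' @param dup data.frame from \code{\link{duplication_frequency}} (or a
#'   \code{size_binned_profile}).
#' @param threshold duplication fraction threshold (default 0.5; the
#'   terminus of chromosome II is conventionally anchored at 0.25).
#' @return the interval center, or \code{NA} if never crossed.
#' @export
first_crossing <- function(dup, threshold = 0.5) {
  frac <- if ("fraction" %in% names(dup)) dup$fraction
          else dup$duplication_fraction
  hit <- which(!is.na(frac) & frac >= threshold)
  if (!length(hit)) NA_real_ else dup$center[min(hit)]
}

#' Rank loci by duplication timing
#'
#' Orders loci by the first interval at which their duplication
#' frequency crosses the threshold; loci crossing in the same interval
#' are tied (flagged) and broken by genomic distance from their
#' chromosome's origin when locus annotations are available.
#'
#' @param dups named list of duplication-frequency data.frames (names =
#'   locus/channel).
#' @param loci optional named list of \code{\link{locus}} objects.
#' @param genome a \code{\link{genome_map}} (used with \code{loci}).
#' @param threshold crossing threshold.
#' @return data.frame with columns \code{locus}, \code{crossing},
#'   \code{dist_from_ori_kb}, \code{tied}, sorted in duplication order.
#' @export
rank_loci_by_duplication <- function(dups, loci = NULL,
                                     genome = vc_genome_map(),
                                     threshold = 0.5) {
  cross <- vapply(dups, first_crossing, numeric(1),
                  threshold = threshold)
  d_ori <- rep(NA_real_, length(dups))
  if (!is.null(loci)) {
    d_ori <- vapply(names(dups), function(nm) {
      loc <- loci[[nm]]
      if (is.null(loc)) return(NA_real_)
      chr <- genome$chromosomes[[loc$chromosome]]
      arm_path(loc$map_position_kb, chr)$dist_kb
    }, numeric(1))
  }
  ord <- order(cross, d_ori, na.last = TRUE)
  out <- data.frame(locus = names(dups)[ord], crossing = cross[ord],
                    dist_from_ori_kb = d_ori[ord],
                    stringsAsFactors = FALSE)
  out$tied <- duplicated(out$crossing) |
    duplicated(out$crossing, fromLast = TRUE)
  rownames(out) <- NULL
  out
}
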