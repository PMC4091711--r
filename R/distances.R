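pctl_summary <- function(d, pair, n_label = "n_cells") {
  qs <- if (length(d)) stats::quantile(d, c(0.05, 0.25, 0.5, 0.75, 0.95),
                                       names = FALSE, type = 7)
        else rep(NA_real_, 5)
  out <- data.frame(pair = pair, n_cells = length(d),
                    p5 = qs[1], p25 = qs[2], median = qs[3],
                    p75 = qs[4], p95 = qs[5], stringsAsFactors = FALSE)
  class(out) <- c("distance_summary", "data.frame")
  out
}

# per-cell relative positions of a channel restricted to a focus count
rel_by_count <- function(ds, channel, count) {
  cnt <- focus_count(ds, channel)
  keep <- ds$cells$cell_id[cnt == count]
  ft <- focus_table(ds, channel)
  ft[ft$cell_id %in% keep, , drop = FALSE]
}

#' Inter-locus relative distance
#'
#' Over cells with exactly one focus in each channel, the axial
#' distance between the two foci as a fraction of cell length,
#' summarised by percentiles (5/25/50/75/95).  Orientation-free.
#'
#' @param ds a \code{\link{strain_dataset}}.
#' @param chA,chB channel names.
#' @return a one-row \code{distance_summary} data.frame.
#' @export
interlocus_distance <- function(ds, chA, chB) {
  d <- interlocus_distances_raw(ds, chA, chB)
  if (!nrow(d)) stop("no cells with exactly one focus of each channel")
  pctl_summary(d$dist, paste0(chA, ":", chB))
}

interlocus_distances_raw <- function(ds, chA, chB) {
  fa <- rel_by_count(ds, chA, 1L)
  fb <- rel_by_count(ds, chB, 1L)
  common <- intersect(fa$cell_id, fb$cell_id)
  fa <- fa[match(common, fa$cell_id), , drop = FALSE]
  fb <- fb[match(common, fb$cell_id), , drop = FALSE]
  # micrometre difference first: |x_A - x_B| is exactly mirror-invariant
  data.frame(cell_id = common,
             bin_length_um = fa$bin_length_um,
             dist = abs(fa$position_um - fb$position_um) / fa$length_um,
             stringsAsFactors = FALSE)
}

#' Sister-locus relative distance
#'
#' Over cells longer than \code{min_length_um} (strict) with exactly
#' two foci in the channel, the relative distance between the sister
#' foci, summarised by percentiles.  Orientation-free.
#'
#' @param ds a \code{\link{strain_dataset}}.
#' @param channel channel name.
#' @param min_length_um strict lower length cutoff (um).
#' @return a one-row \code{distance_summary} data.frame.
#' @export
sister_distance <- function(ds, channel, min_length_um = 3.4) {
  ft <- rel_by_count(ds, channel, 2L)
  ft <- ft[ft$length_um > min_length_um, , drop = FALSE]
  if (!nrow(ft)) stop("no qualifying two-focus cells")
  d <- vapply(split(seq_len(nrow(ft)), ft$cell_id), function(i)
    abs(ft$position_um[i[1]] - ft$position_um[i[2]]) / ft$length_um[i[1]],
    numeric(1))
  pctl_summary(unname(d), paste0(channel, ":sisters"))
}

#' Inter-locus distance as a function of cell length
#'
#' The inter-locus distance of \code{\link{interlocus_distance}},
#' grouped by the same 0.1 um interval / 0.3 um sliding-window scheme as
#' the choreography statistics.  Windows with fewer than
#' \code{min_cells} qualifying cells are masked.
#'
#' @inheritParams interlocus_distance
#' @param interval_width_um,window_um,min_cells windowing parameters.
#' @return data.frame: one row per window center with percentile
#'   columns; masked windows have \code{NA} percentiles.
#' @export
distance_vs_elongation <- function(ds, chA, chB, interval_width_um = 0.1,
                                   window_um = 0.3, min_cells = 10) {
  raw <- interlocus_distances_raw(ds, chA, chB)
  centers <- window_centers(binning_length(ds), interval_width_um)
  rows <- lapply(centers, function(ct) {
    d <- raw$dist[in_window(raw$bin_length_um, ct, window_um)]
    s <- if (length(d) >= min_cells) pctl_summary(d, paste0(chA, ":", chB))
         else pctl_summary(numeric(), paste0(chA, ":", chB))
    s$n_cells <- length(d)
    cbind(center = ct, s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
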