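#' Per-pole most-polar locus statistic
#'
#' In each dividing cell carrying exactly two foci of each of two
#' channels, the cell is split at midcell and each pole is scored
#' independently: the channel whose focus in that half lies closer to
#' the pole is "most polar" there.  A pole is skipped (and counted)
#' unless its half contains exactly one focus of each channel; foci
#' exactly at midcell are assigned to the lower half.  Orientation-free
#' (computed per pole, not on the oriented axis).
#'
#' @param ds a \code{\link{strain_dataset}}.
#' @param chA,chB channel names (the proportion reported is for
#'   \code{chA}).
#' @param dividing_length_threshold minimum cell length (um); default
#'   the 90th percentile of binning lengths.
#' @param tie_tolerance ties: equal pole distances within
#'   \code{tie_tolerance * L} count to the tie bucket, not to either
#'   channel.
#' @return object of class \code{polarity_count}: \code{n_poles},
#'   \code{n_A_most_polar}, \code{n_B_most_polar}, \code{n_ties},
#'   \code{n_skipped_poles}, \code{proportion_A}.
#' @export
per_pole_most_polar <- function(ds, chA, chB,
                                dividing_length_threshold = NULL,
                                tie_tolerance = 0.01) {
  if (is.null(dividing_length_threshold))
    dividing_length_threshold <- stats::quantile(binning_length(ds), 0.9,
                                                 names = FALSE, type = 7)
  cntA <- focus_count(ds, chA)
  cntB <- focus_count(ds, chB)
  div <- binning_length(ds) >= dividing_length_threshold &
    cntA == 2L & cntB == 2L
  ids <- ds$cells$cell_id[div]
  if (!length(ids)) stop("no qualifying dividing cells")
  fa <- ds$foci[ds$foci$channel == chA & ds$foci$cell_id %in% ids, ]
  fb <- ds$foci[ds$foci$channel == chB & ds$foci$cell_id %in% ids, ]
  spA <- split(fa$position_um, factor(fa$cell_id, levels = ids))
  spB <- split(fb$position_um, factor(fb$cell_id, levels = ids))
  L <- ds$cells$length_um[div]

  nA <- nB <- nt <- nskip <- 0L
  for (i in seq_along(ids)) {
    a <- spA[[i]]; b <- spB[[i]]; len <- L[i]
    # halves: lower [0, L/2] (midcell inclusive, fixed tie-break), upper
    lowA <- a <= len / 2; lowB <- b <= len / 2
    for (pole in c("lower", "upper")) {
      selA <- if (pole == "lower") a[lowA] else a[!lowA]
      selB <- if (pole == "lower") b[lowB] else b[!lowB]
      if (length(selA) != 1L || length(selB) != 1L) {
        nskip <- nskip + 1L
        next
      }
      dA <- if (pole == "lower") selA else len - selA
      dB <- if (pole == "lower") selB else len - selB
      if (abs(dA - dB) <= tie_tolerance * len) nt <- nt + 1L
      else if (dA < dB) nA <- nA + 1L
      else nB <- nB + 1L
    }
  }
  structure(list(pair = paste0(chA, ":", chB),
                 dividing_length_threshold = dividing_length_threshold,
                 n_poles = nA + nB + nt,
                 n_A_most_polar = nA, n_B_most_polar = nB, n_ties = nt,
                 n_skipped_poles = nskip,
                 proportion_A = if (nA + nB > 0) nA / (nA + nB)
                                else NA_real_),
            class = "polarity_count")
}

#' @export
print.polarity_count <- function(x, ...) {
  cat(sprintf("<polarity_count> %s: %d poles, A %d / B %d / ties %d (prop A %.3f)\n",
              x$pair, x$n_poles, x$n_A_most_polar, x$n_B_most_polar,
              x$n_ties, x$proportion_A))
  invisible(x)
}

#' Polarity summary with binomial confidence interval
#'
#' Wilson 95\% score interval for the most-polar proportion; warns when
#' fewer poles were scored than two per target cell.
#'
#' @param counts a \code{polarity_count}.
#' @param n_target intended number of scored cells (two poles each).
#' @return list with \code{proportion}, \code{ci_low}, \code{ci_high},
#'   \code{n_poles}, \code{n_ties}, \code{warning} (character or
#'   \code{NULL}).
#' @export
polarity_report <- function(counts, n_target = 100) {
  stopifnot(inherits(counts, "polarity_count"))
  n <- counts$n_A_most_polar + counts$n_B_most_polar
  if (n == 0)
    return(list(proportion = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, n_poles = 0L,
                n_ties = counts$n_ties, warning = "no scored poles"))
  ci <- wilson_ci(counts$n_A_most_polar, n)
  warn <- NULL
  if (counts$n_poles < 2 * n_target) {
    warn <- sprintf("only %d poles scored (target %d)",
                    counts$n_poles, 2 * n_target)
    warning(warn)
  }
  list(proportion = counts$n_A_most_polar / n,
       ci_low = ci[1], ci_high = ci[2], n_poles = counts$n_poles,
       n_ties = counts$n_ties, warning = warn)
}

# Wilson 95% score interval
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}
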