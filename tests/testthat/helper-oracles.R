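# independent brute-force oracles for the sliding-window statistics.
# deliberately written as plain per-window loops over raw vectors, with
# no shared code with the package internals.

oracle_centers <- function(binL, width = 0.1) {
  ks <- floor(min(binL) / width + 1e-9):floor(max(binL) / width + 1e-9)
  ks * width
}

# duplication fraction per window: pool cells with binning length in
# [c - w/2, c + w/2), fraction = #2-focus / (#1-focus + #2-focus)
oracle_duplication <- function(binL, counts, width = 0.1, window = 0.3,
                               min_cells = 10) {
  centers <- oracle_centers(binL, width)
  res <- data.frame(center = centers, n_1focus = NA_integer_,
                    n_2focus = NA_integer_, fraction = NA_real_)
  for (i in seq_along(centers)) {
    n1 <- 0L; n2 <- 0L
    for (j in seq_along(binL)) {
      if (binL[j] >= centers[i] - window / 2 &&
          binL[j] < centers[i] + window / 2) {
        if (counts[j] == 1L) n1 <- n1 + 1L
        if (counts[j] == 2L) n2 <- n2 + 1L
      }
    }
    res$n_1focus[i] <- n1
    res$n_2focus[i] <- n2
    if (n1 + n2 >= min_cells) res$fraction[i] <- n2 / (n1 + n2)
  }
  res
}

# per-window position percentiles of the dominant type; rel is a list of
# oriented relative position vectors, one per cell.  The percentile
# definition (interpolating type-7 quantile) is part of the statistic's
# definition; the windowing and pooling are what this oracle recomputes.
oracle_q50 <- function(x) unname(stats::quantile(x, 0.5, type = 7))

oracle_profile_medians <- function(binL, rel, width = 0.1, window = 0.3,
                                   min_cells = 10, dom = 0.5) {
  centers <- oracle_centers(binL, width)
  out <- list()
  for (i in seq_along(centers)) {
    in_win <- which(binL >= centers[i] - window / 2 &
                    binL < centers[i] + window / 2)
    nf <- lengths(rel[in_win])
    n1 <- sum(nf == 1L); n2 <- sum(nf == 2L)
    if (n1 + n2 < min_cells) {
      out[[i]] <- data.frame(center = centers[i], type = NA_character_,
                             med = NA_real_, lo = NA_real_,
                             up = NA_real_)
      next
    }
    if (n2 / (n1 + n2) >= dom) {
      pairs <- rel[in_win][nf == 2L]
      lo <- sapply(pairs, min); up <- sapply(pairs, max)
      out[[i]] <- data.frame(center = centers[i], type = "two",
                             med = NA_real_,
                             lo = oracle_q50(lo),
                             up = oracle_q50(up))
    } else {
      xs <- unlist(rel[in_win][nf == 1L])
      out[[i]] <- data.frame(center = centers[i], type = "one",
                             med = oracle_q50(xs), lo = NA_real_,
                             up = NA_real_)
    }
  }
  do.call(rbind, out)
}

# per-window percentile summary of inter-locus distances
oracle_windowed_distance <- function(binL_cell, dist, centers,
                                     window = 0.3, min_cells = 10) {
  res <- data.frame(center = centers, n = NA_integer_,
                    median = NA_real_)
  for (i in seq_along(centers)) {
    d <- dist[binL_cell >= centers[i] - window / 2 &
              binL_cell < centers[i] + window / 2]
    res$n[i] <- length(d)
    if (length(d) >= min_cells) res$median[i] <- oracle_q50(d)
  }
  res
}
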