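# small hand-built datasets -------------------------------------------------

# cells: numeric lengths; foci: list per cell of named channel lists,
# e.g. list(A = c(1.0), B = c(0.5, 1.5))
tiny_dataset <- function(lengths, foci_spec, oriented = FALSE) {
  ids <- sprintf("c%02d", seq_along(lengths))
  cells <- data.frame(cell_id = ids, length_um = lengths,
                      stringsAsFactors = FALSE)
  if (oriented) {
    cells$orientation <- "oriented"
    cells$polarity_flip <- FALSE
  }
  rows <- list()
  for (i in seq_along(foci_spec)) {
    for (ch in names(foci_spec[[i]])) {
      p <- foci_spec[[i]][[ch]]
      if (length(p))
        rows[[length(rows) + 1L]] <-
          data.frame(cell_id = ids[i], channel = ch, position_um = p,
                     stringsAsFactors = FALSE)
    }
  }
  strain_dataset("tiny", cells, do.call(rbind, rows))
}

# WT simulation shared across test files (computed once per run)
wt_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- sample_population(preset_scenario("WT"), 800, seed = 11)
    cache
  }
})

wt_oriented <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- refine_orientation(orient_cells(wt_sim()$dataset))
    cache
  }
})
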