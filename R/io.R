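#' Read a per-cell focus table
#'
#' Parses a delimited text table (tab or comma; auto-detected) with one
#' row per segmented cell.  The schema names the length column and, per
#' fluorescent channel, the column holding that channel's focus
#' positions.  A focus column holds zero or more axial positions in
#' micrometres separated by \code{";"} (an empty cell means no focus).
#'
#' Rows with a missing or non-numeric length are rejected, as are rows
#' with any focus position outside \code{[0, length]}; rejected counts
#' are reported via a warning.
#'
#' @param path file path.
#' @param schema list with elements \code{length_col} (mandatory),
#'   \code{channels} (named list or character vector: channel name ->
#'   column name) and optionally \code{id_col}.
#' @param channel_locus_map optional channel -> \code{\link{locus}} map
#'   stored on the dataset.
#' @param strain_id identifier; defaults to the file name.
#' @return A validated \code{\link{strain_dataset}}.
#' @export
read_cell_table <- function(path, schema, channel_locus_map = list(),
                            strain_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(strain_id)) strain_id <- sub("\\.[^.]*$", "", basename(path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  chan_cols <- unlist(schema$channels)
  if (is.null(names(chan_cols)) || any(names(chan_cols) == ""))
    names(chan_cols) <- chan_cols
  need <- c(schema$length_col, chan_cols)
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing mandatory columns: ", paste(miss, collapse = ", "))

  if (!nrow(tab)) {
    return(strain_dataset(strain_id,
      cells = data.frame(cell_id = character(), length_um = numeric()),
      foci = NULL, channel_locus_map = channel_locus_map))
  }

  len <- suppressWarnings(as.numeric(tab[[schema$length_col]]))
  bad_len <- is.na(len) | len <= 0
  ids <- if (!is.null(schema$id_col) && schema$id_col %in% names(tab))
    tab[[schema$id_col]] else sprintf("cell_%04d", seq_len(nrow(tab)))

  # parse focus columns; flag rows whose foci violate [0, length]
  bad_focus <- rep(FALSE, nrow(tab))
  foci_rows <- vector("list", length(chan_cols))
  parsed <- vector("list", length(chan_cols))
  for (k in seq_along(chan_cols)) {
    raw <- tab[[chan_cols[k]]]
    parsed[[k]] <- lapply(raw, function(s) {
      s <- trimws(s)
      if (is.na(s) || s == "" || s == "NA") return(numeric())
      suppressWarnings(as.numeric(strsplit(s, ";", fixed = TRUE)[[1]]))
    })
    for (r in which(!bad_len)) {
      p <- parsed[[k]][[r]]
      if (any(is.na(p)) || any(p < 0) || any(p > len[r]))
        bad_focus[r] <- TRUE
    }
  }
  keep <- !bad_len & !bad_focus
  n_rej <- sum(!keep)
  if (n_rej > 0)
    warning(sprintf("%s: rejected %d row(s) (%d bad length, %d focus out of range)",
                    basename(path), n_rej, sum(bad_len),
                    sum(bad_focus & !bad_len)))

  cells <- data.frame(cell_id = ids[keep], length_um = len[keep],
                      stringsAsFactors = FALSE)
  if ("orientation" %in% names(tab)) {
    cells$orientation <- tab$orientation[keep]
    if ("polarity_flip" %in% names(tab))
      cells$polarity_flip <- as.logical(tab$polarity_flip[keep])
  }
  fl <- list()
  for (k in seq_along(chan_cols)) {
    ch <- names(chan_cols)[k]
    pos <- parsed[[k]][keep]
    nf <- lengths(pos)
    if (sum(nf))
      fl[[ch]] <- data.frame(cell_id = rep(cells$cell_id, nf),
                             channel = ch, position_um = unlist(pos),
                             stringsAsFactors = FALSE)
  }
  foci <- if (length(fl)) do.call(rbind, fl) else NULL
  strain_dataset(strain_id, cells, foci,
                 channel_locus_map = channel_locus_map)
}

#' Write a strain dataset as a focus table
#'
#' Inverse of \code{\link{read_cell_table}}: one row per cell, per-channel
#' focus positions joined with \code{";"}.  Orientation columns are
#' included so oriented datasets round-trip.
#'
#' @param ds a \code{strain_dataset}.
#' @param path output path (tab-separated).
#' @return \code{path}, invisibly.
#' @export
write_cell_table <- function(ds, path) {
  chans <- sort(unique(ds$foci$channel))
  out <- data.frame(cell_id = ds$cells$cell_id,
                    length_um = format_num(ds$cells$length_um),
                    stringsAsFactors = FALSE)
  for (ch in chans) {
    f <- ds$foci[ds$foci$channel == ch, , drop = FALSE]
    sp <- split(f$position_um, factor(f$cell_id, levels = ds$cells$cell_id))
    out[[ch]] <- vapply(sp, function(p) paste(format_num(p), collapse = ";"),
                        character(1))
  }
  out$orientation <- ds$cells$orientation
  out$polarity_flip <- ds$cells$polarity_flip
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

format_num <- function(x) formatC(x, digits = 10, format = "g")

# default schema matching write_cell_table output
default_schema <- function(channels) {
  list(length_col = "length_um", id_col = "cell_id",
       channels = stats::setNames(as.list(channels), channels))
}

#' Write a profile or summary table
#'
#' Writes any of the pipeline's tabular results (size-binned profiles,
#' distance summaries, polarity counts) as tab-separated text with a
#' stable column order, round-trippable with
#' \code{\link{read_profile_table}}.
#'
#' @param x data.frame (e.g. a \code{size_binned_profile}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_profile_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a profile table written by \code{write_profile_table}
#' @param path file path.
#' @return data.frame.
#' @export
read_profile_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
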