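#' Run the full analysis pipeline from a configuration
#'
#' Drives simulate (optional) -> orient -> profiles -> realign
#' (multi-strain) -> distances -> polarity, writing per-statistic TSV
#' tables and a single machine-readable JSON summary.  Reruns with the
#' same configuration and seed produce byte-identical outputs.
#'
#' @param config a list, or a path to a YAML/JSON configuration file,
#'   with elements:
#'   \describe{
#'     \item{\code{outdir}}{output directory (created).}
#'     \item{\code{seed}}{simulation master seed.}
#'     \item{\code{strains}}{list; each entry has \code{id} and either
#'       \code{simulate} (\code{scenario}, \code{n}, optional
#'       \code{parS_kb}, \code{loci}) or \code{input} + \code{schema}
#'       (see \code{\link{read_cell_table}}).}
#'     \item{\code{align}}{optional: \code{ref} strain id and
#'       \code{anchor} (see \code{\link{compute_offset}}).}
#'     \item{\code{distances}}{optional list of channel pairs.}
#'     \item{\code{sister_distances}}{optional channel vector.}
#'     \item{\code{polarity}}{optional list of channel pairs.}
#'     \item{\code{interval_width_um}, \code{window_um},
#'       \code{min_cells}, \code{dominant_threshold},
#'       \code{sister_min_length_um}, \code{ambiguity_tolerance}}{
#'       thresholds; defaults as in the stage functions.}
#'   }
#' @return (invisibly) the report bundle: datasets, profiles, summaries
#'   and the path of the JSON summary.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  p <- function(x, d) if (is.null(x)) d else x
  iw <- p(config$interval_width_um, 0.1)
  ww <- p(config$window_um, 0.3)
  mc <- p(config$min_cells, 10)
  dom <- p(config$dominant_threshold, 0.5)
  smin <- p(config$sister_min_length_um, 3.4)
  atol <- p(config$ambiguity_tolerance, 0.1)
  seed <- p(config$seed, 1)
  outdir <- config$outdir
  if (is.null(outdir)) stop("[config] outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config$strains) || !length(config$strains))
    stop("[config] at least one strain is required")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  summary <- list(seed = seed,
                  thresholds = list(interval_width_um = iw,
                                    window_um = ww, min_cells = mc,
                                    dominant_threshold = dom,
                                    sister_min_length_um = smin,
                                    ambiguity_tolerance = atol))
  datasets <- list()
  truths <- list()

  for (k in seq_along(config$strains)) {
    sc <- config$strains[[k]]
    id <- p(sc$id, paste0("strain", k))
    ds <- stage(paste0("load:", id), {
      if (!is.null(sc$simulate)) {
        s <- sc$simulate
        scn <- preset_scenario(s$scenario,
                               parS_kb = s$parS_kb,
                               loci = unlist(s$loci) %||% NULL)
        sim <- sample_population(scn, p(s$n, 800),
                                 seed = seed + k - 1)
        truths[[id]] <- sim$truth
        d <- sim$dataset
        d$strain_id <- id
        d
      } else if (!is.null(sc$input)) {
        read_cell_table(sc$input, sc$schema, strain_id = id)
      } else stop("strain needs 'simulate' or 'input'")
    })
    ds <- stage(paste0("orient:", id), {
      d <- orient_cells(ds, ambiguity_tolerance = atol)
      refine_orientation(d)
    })
    datasets[[id]] <- ds
    rep <- validate_dataset(ds)
    summary$strains[[id]] <- list(
      n_cells = rep$n_cells,
      n_oriented = sum(ds$cells$orientation == "oriented"),
      n_ambiguous = sum(ds$cells$orientation == "ambiguous"),
      length_range_um = rep$length_range_um,
      unmapped_channels = rep$unmapped_channels)
  }

  # cross-strain realignment against the reference strain
  if (!is.null(config$align)) {
    al <- config$align
    ref_id <- p(al$ref, names(datasets)[1])
    if (is.null(datasets[[ref_id]]))
      stop("[align] unknown reference strain: ", ref_id)
    for (id in setdiff(names(datasets), ref_id)) {
      off <- stage(paste0("align:", id), {
        o <- compute_offset(datasets[[ref_id]], datasets[[id]],
                            al$anchor, iw, ww, mc)
        datasets[[id]] <- apply_offset(datasets[[id]], o)
        o
      })
      summary$alignment[[id]] <- list(ref = ref_id,
                                      anchor = al$anchor,
                                      offset_um = off$offset_um)
    }
  }

  profiles <- list()
  for (id in names(datasets)) {
    ds <- datasets[[id]]
    for (ch in sort(unique(ds$foci$channel))) {
      prof <- stage(paste0("profile:", id, ":", ch),
                    position_profile(ds, ch, iw, ww, mc, dom))
      profiles[[paste(id, ch, sep = ".")]] <- prof
      write_profile_table(prof,
        file.path(outdir, sprintf("profile_%s_%s.tsv", id, ch)))
      summary$crossings[[id]][[ch]] <- first_crossing(prof, dom)
    }
  }

  first_ds <- datasets[[1]]
  for (pr in config$distances %||% list()) {
    key <- paste(pr[[1]], pr[[2]], sep = ":")
    dsum <- stage(paste0("distances:", key),
                  interlocus_distance(first_ds, pr[[1]], pr[[2]]))
    write_profile_table(dsum,
      file.path(outdir, sprintf("dist_%s_%s.tsv", pr[[1]], pr[[2]])))
    summary$distances[[key]] <- as.list(dsum)
  }
  for (ch in unlist(config$sister_distances) %||% character()) {
    dsum <- stage(paste0("sisterdist:", ch),
                  sister_distance(first_ds, ch, smin))
    write_profile_table(dsum,
      file.path(outdir, sprintf("sisterdist_%s.tsv", ch)))
    summary$sister_distances[[ch]] <- as.list(dsum)
  }
  for (pr in config$polarity %||% list()) {
    key <- paste(pr[[1]], pr[[2]], sep = ":")
    pc <- stage(paste0("polarity:", key),
                per_pole_most_polar(first_ds, pr[[1]], pr[[2]]))
    summary$polarity[[key]] <- unclass(pc)
  }

  json_path <- file.path(outdir, "run_summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(list(datasets = datasets, truths = truths,
                 profiles = profiles, summary = summary,
                 summary_path = json_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_config <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path)
  else yaml::read_yaml(path)
}

#' Write tiny hand-constructed fixture datasets
#'
#' Small focus tables (<= 20 cells each) with analytically known
#' statistics, used by the test suite and as worked examples:
#' \code{fixture_basic.tsv} (duplication and position expectations),
#' \code{fixture_polarity.tsv} (most-polar proportion exactly 1),
#' \code{fixture_realign_ref.tsv} / \code{fixture_realign_target.tsv}
#' (a pure +0.2 um length shift).  Expected values are written to
#' \code{fixture_expectations.json}.
#'
#' @param outdir writable directory (created).
#' @return (invisibly) named list of file paths.
#' @export
make_fixtures <- function(outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  # basic: 6 cells, channel A; window at 2.0 holds lengths 1.9-2.1:
  # counts (1,1,2) -> duplication fraction 1/3; single-focus medians known
  cells <- data.frame(
    cell_id = sprintf("c%02d", 1:6),
    length_um = c(1.95, 2.00, 2.05, 3.50, 3.55, 3.60))
  foci <- rbind(
    data.frame(cell_id = "c01", channel = "A", position_um = 0.39),
    data.frame(cell_id = "c02", channel = "A", position_um = 1.00),
    data.frame(cell_id = "c03", channel = "A",
               position_um = c(0.41, 1.845)),
    data.frame(cell_id = "c04", channel = "A",
               position_um = c(0.35, 3.15)),
    data.frame(cell_id = "c05", channel = "A",
               position_um = c(0.355, 3.195)),
    data.frame(cell_id = "c06", channel = "A",
               position_um = c(0.36, 3.24)))
  basic <- strain_dataset("fixture_basic", cells, foci)
  paths$basic <- file.path(outdir, "fixture_basic.tsv")
  write_cell_table(basic, paths$basic)

  # polarity: channel A strictly most polar at all four poles
  pcells <- data.frame(cell_id = c("p1", "p2"), length_um = c(4.0, 4.0))
  pfoci <- rbind(
    data.frame(cell_id = "p1", channel = "A",
               position_um = c(0.2, 3.9)),
    data.frame(cell_id = "p1", channel = "B",
               position_um = c(0.9, 3.0)),
    data.frame(cell_id = "p2", channel = "A",
               position_um = c(0.1, 3.8)),
    data.frame(cell_id = "p2", channel = "B",
               position_um = c(0.8, 3.1)))
  pol <- strain_dataset("fixture_polarity", pcells, pfoci)
  paths$polarity <- file.path(outdir, "fixture_polarity.tsv")
  write_cell_table(pol, paths$polarity)

  # realignment pair: identical populations, target lengths +0.2 um;
  # lengths placed away from window boundaries so binning is unambiguous
  lens <- seq(2.03, 3.93, by = 0.1)
  n2 <- lens >= 3.0
  rcells <- data.frame(cell_id = sprintf("r%02d", seq_along(lens)),
                       length_um = lens)
  rfoci <- do.call(rbind, lapply(seq_along(lens), function(i) {
    pos <- if (n2[i]) c(0.25, 0.75) * lens[i] else 0.5 * lens[i]
    data.frame(cell_id = rcells$cell_id[i], channel = "A",
               position_um = pos)
  }))
  ref <- strain_dataset("fixture_realign_ref", rcells, rfoci)
  tcells <- rcells
  tcells$length_um <- tcells$length_um + 0.2
  tfoci <- rfoci
  tfoci$position_um <- tfoci$position_um *
    rep((tcells$length_um / rcells$length_um), ifelse(n2, 2, 1))
  tgt <- strain_dataset("fixture_realign_target", tcells, tfoci)
  paths$realign_ref <- file.path(outdir, "fixture_realign_ref.tsv")
  paths$realign_target <- file.path(outdir, "fixture_realign_target.tsv")
  write_cell_table(ref, paths$realign_ref)
  write_cell_table(tgt, paths$realign_target)

  expectations <- list(
    basic = list(window_2.0_counts = c(n_1focus = 2, n_2focus = 1),
                 window_2.0_fraction = 1 / 3,
                 window_2.0_single_median = 0.35,
                 window_3.5_fraction = 1.0,
                 window_3.5_lower_median = 0.1,
                 window_3.5_upper_median = 0.9),
    polarity = list(proportion_A = 1.0, n_poles = 4),
    realign = list(offset_um = -0.2))
  paths$expectations <- file.path(outdir, "fixture_expectations.json")
  jsonlite::write_json(expectations, paths$expectations,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
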