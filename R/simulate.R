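#' Cell-cycle model
#'
#' Slow-growth cycle with a fixed generation time split into a
#' pre-replication B period, a replication C period and a
#' post-replication D period.
#'
#' @param tau_min generation time in minutes.
#' @param B_min,C_min,D_min period durations in minutes; must sum to
#'   \code{tau_min}.
#' @return object of class \code{cell_cycle_model}.
#' @export
cell_cycle_model <- function(tau_min = 55, B_min = 11, C_min = 32,
                             D_min = 12) {
  stopifnot(tau_min > 0, B_min >= 0, C_min >= 0, D_min >= 0,
            isTRUE(all.equal(B_min + C_min + D_min, tau_min)))
  structure(list(tau_min = tau_min, B_min = B_min, C_min = C_min,
                 D_min = D_min), class = "cell_cycle_model")
}

#' Growth model
#'
#' Exponential elongation: a cell born at length \eqn{L_b} has length
#' \eqn{L_b 2^{a/\tau}} at age \eqn{a}, so division length is about
#' twice birth length.
#'
#' @param birth_length_mean_um,birth_length_sd_um birth length
#'   distribution (Gaussian), micrometres.
#' @param growth_law only \code{"exponential"} is supported.
#' @return object of class \code{growth_model}.
#' @export
growth_model <- function(birth_length_mean_um = 2.05,
                         birth_length_sd_um = 0.07,
                         growth_law = "exponential") {
  stopifnot(birth_length_mean_um > 0, birth_length_sd_um >= 0,
            growth_law == "exponential")
  structure(list(birth_length_mean_um = birth_length_mean_um,
                 birth_length_sd_um = birth_length_sd_um,
                 growth_law = growth_law), class = "growth_model")
}

#' Replication model
#'
#' Bidirectional replication from each active origin at constant fork
#' speed.  The fork speed is set so that the longest chromosome-I
#' replichore completes in exactly the C period; chromosome II fires
#' late enough that both chromosomes terminate together at the end of
#' the C period (termination synchrony).
#'
#' @param genome a \code{\link{genome_map}}.
#' @param cycle a \code{\link{cell_cycle_model}}.
#' @param extra_origins named list (by chromosome) of additional origin
#'   positions in kb, e.g. \code{list(I = 651)} for an ectopic origin.
#' @return object of class \code{replication_model} with per-chromosome
#'   origin lists and initiation ages, and the shared
#'   \code{fork_speed_kb_per_min}.
#' @export
replication_model <- function(genome = vc_genome_map(),
                              cycle = cell_cycle_model(),
                              extra_origins = list()) {
  chrs <- genome$chromosomes
  arm_max <- function(chr) {
    fwd <- (chr$dif_kb - chr$ori_kb) %% chr$length_kb
    max(fwd, chr$length_kb - fwd)
  }
  fork <- arm_max(chrs[["I"]]) / cycle$C_min
  per_chr <- list()
  for (nm in names(chrs)) {
    chr <- chrs[[nm]]
    init <- if (nm == "I") cycle$B_min
            else cycle$B_min + cycle$C_min - arm_max(chr) / fork
    origins <- c(chr$ori_kb, extra_origins[[nm]])
    per_chr[[nm]] <- list(origins = origins, initiation_age_min = init)
  }
  stopifnot(per_chr[["II"]]$initiation_age_min >=
              per_chr[["I"]]$initiation_age_min)
  structure(list(fork_speed_kb_per_min = fork, chromosomes = per_chr),
            class = "replication_model")
}

#' Replication time of a locus
#'
#' Cell age (minutes) at which a locus is replicated: the earliest
#' arrival over active origins of \code{initiation age + genomic
#' distance / fork speed}, with distances measured along the circular
#' map (converging forks).  Terminus loci therefore replicate last on
#' their chromosome.
#'
#' @param locus a \code{\link{locus}} (or its name if \code{panel}
#'   given).
#' @param replication a \code{\link{replication_model}}.
#' @param genome a \code{\link{genome_map}}.
#' @param panel optional named locus list used to resolve a name.
#' @return replication age in minutes.
#' @export
replication_time <- function(locus, replication = replication_model(),
                             genome = vc_genome_map(), panel = NULL) {
  if (is.character(locus)) {
    if (is.null(panel)) panel <- vc_locus_panel(genome)
    locus <- panel[[locus]]
    if (is.null(locus)) stop("unknown locus name")
  }
  chr <- genome$chromosomes[[locus$chromosome]]
  rc <- replication$chromosomes[[locus$chromosome]]
  if (is.null(chr) || is.null(rc))
    stop("locus chromosome not in replication model")
  d <- circ_dist_kb(locus$map_position_kb, rc$origins, chr$length_kb)
  min(rc$initiation_age_min + d / replication$fork_speed_kb_per_min)
}

#' Sample steady-state cell ages
#'
#' In a steady-state exponentially growing population the cell-age
#' density is \eqn{f(a) = (2\ln 2/\tau)\,2^{-a/\tau}} on \eqn{[0,\tau)},
#' with CDF \eqn{F(a) = 2(1 - 2^{-a/\tau})}.  Sampling is by CDF
#' inversion.
#'
#' @param n number of ages.
#' @param tau_min generation time (minutes).
#' @param seed optional integer; if given, seeds the RNG.
#' @return numeric vector of ages in \code{[0, tau_min)}.
#' @export
steady_state_ages <- function(n, tau_min = 55, seed = NULL) {
  stopifnot(n >= 1, tau_min > 0)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  -tau_min * log2(1 - u / 2)
}

#' Sister home positions after division mapping
#'
#' A locus at relative pre-duplication home \eqn{h} (0 = new pole)
#' segregates to sister homes \eqn{h_{old} = 1/2 + h/2} (old-pole
#' daughter's copy) and \eqn{h_{new} = 1/2 - h/2}.  This affine mapping
#' is the unique choice that makes the pattern self-similar across
#' divisions: in each daughter's own frame the copy returns to \eqn{h}.
#'
#' @param h_pre relative home position in (0, 1).
#' @return named numeric vector \code{c(old = ..., new = ...)}.
#' @export
sister_homes <- function(h_pre) {
  c(old = 0.5 + h_pre / 2, new = 0.5 - h_pre / 2)
}

#' Map a mother-frame coordinate into a daughter frame
#'
#' The old-pole daughter inherits the mother's \code{[0.5, 1]} half
#' (its new pole is the septum at 0.5); the new-pole daughter inherits
#' \code{[0, 0.5]} (its new pole is the septum, its old pole the
#' mother's new pole at 0).
#'
#' @param x relative position in the mother frame (0 = mother's new
#'   pole).
#' @param half \code{"old"} or \code{"new"}: which daughter.
#' @return relative position in the daughter frame (0 = daughter's new
#'   pole).
#' @export
daughter_coordinate <- function(x, half = c("old", "new")) {
  half <- match.arg(half)
  if (half == "old") 2 * x - 1 else 1 - 2 * x
}

# noiseless pre-duplication position of one program row at given ages;
# midcell_early loci ramp linearly to 0.5 over ramp_min ending at
# midcell_age_min
pre_split_position <- function(age, row) {
  if (row$mode == "static") return(rep(row$h_pre, length(age)))
  start <- row$midcell_age_min - row$ramp_min
  frac <- pmin(pmax((age - start) / row$ramp_min, 0), 1)
  row$h_pre + frac * (0.5 - row$h_pre)
}

# resolve sister homes for a program row (optional override)
row_homes <- function(row) {
  if (!is.na(row$home_old)) c(row$home_old, row$home_new)
  else unname(sister_homes(row$h_pre))
}

#' Noiseless locus position(s) at a given age
#'
#' Before duplication a locus sits at its (possibly age-dependent) home
#' position.  After duplication, sisters travel linearly from the
#' position they occupied at the split to their two post-segregation
#' homes over \code{seg_transition_um} of cell elongation.
#'
#' @param locus locus name present in \code{scenario$program}.
#' @param age cell age in minutes.
#' @param scenario a \code{\link{scenario}}.
#' @param split_age age at which sister foci separated; \code{NULL} or
#'   greater than \code{age} means not yet duplicated.
#' @param birth_length birth length of the cell (um); defaults to the
#'   scenario's mean birth length.
#' @return numeric vector of one (pre-split) or two (old-pole sister
#'   first) relative positions on the 0 = new pole axis.
#' @export
position_at_age <- function(locus, age, scenario, split_age = NULL,
                            birth_length = NULL) {
  row <- program_row(scenario$program, locus)
  if (is.null(birth_length))
    birth_length <- scenario$growth$birth_length_mean_um
  if (is.null(split_age) || age < split_age)
    return(pre_split_position(age, row))
  tau <- scenario$cycle$tau_min
  s <- pre_split_position(split_age, row)
  homes <- row_homes(row)
  dl <- birth_length * (2^(age / tau) - 2^(split_age / tau))
  f <- min(max(dl / scenario$seg_transition_um, 0), 1)
  s + f * (homes - s)
}

program_row <- function(program, locus) {
  i <- match(locus, program$locus)
  if (is.na(i)) stop("locus not in position program: ", locus)
  program[i, , drop = FALSE]
}

# per-cell cohesion delays (minutes).  "exp": exponential with the given
# mean.  "div_fraction": exponential whose mean is set so that the given
# fraction of visibly dividing cells carries two foci; the reference age
# is the middle of the D period (when septation is apparent),
# P(t_rep + delay <= tau - D/2) = target.
sample_cohesion <- function(n, row, t_rep, cycle) {
  if (row$cohesion_type == "exp") {
    m <- row$cohesion_par
  } else if (row$cohesion_type == "div_fraction") {
    a_div <- cycle$tau_min - cycle$D_min / 2
    if (t_rep >= a_div) stop("locus replicates after the dividing age")
    m <- -(a_div - t_rep) / log(1 - row$cohesion_par)
  } else stop("unknown cohesion type")
  if (m <= 0) return(rep(0, n))
  stats::rexp(n, rate = 1 / m)
}

# axial coordinates are stored on a dyadic ~1 nm grid (2^-20 um), the
# scale of localisation precision; on this grid L - x is exact in
# floating point, so flipping a stored axis is exactly invertible
quantize_um <- function(x) round(x * 2^20) / 2^20

#' Focus count and positions for one cell
#'
#' A locus shows two foci once the cell's age exceeds its replication
#' time plus a sampled cohesion delay; positions follow
#' \code{\link{position_at_age}} plus Gaussian localisation noise,
#' clamped away from the poles.  Uses the current RNG stream.
#'
#' @param locus locus name in the scenario program.
#' @param age cell age (minutes), in \code{[0, tau)}.
#' @param scenario a \code{\link{scenario}}.
#' @param birth_length birth length (um); default mean birth length.
#' @return list with \code{count} (1 or 2), \code{positions} (relative,
#'   0 = new pole) and \code{split_age}.
#' @export
focus_state <- function(locus, age, scenario, birth_length = NULL) {
  row <- program_row(scenario$program, locus)
  t_rep <- locus_t_rep(row, scenario)
  delay <- sample_cohesion(1, row, t_rep, scenario$cycle)
  split_age <- t_rep + delay
  pos <- position_at_age(locus, age, scenario,
                         split_age = if (age >= split_age) split_age,
                         birth_length = birth_length)
  pos <- clamp_pos(pos + stats::rnorm(length(pos), 0, row$noise_sd))
  list(count = length(pos), positions = pos, split_age = split_age)
}

locus_t_rep <- function(row, scenario) {
  loc <- structure(list(name = row$locus, chromosome = row$chromosome,
                        map_position_kb = row$kb, arm = row$arm),
                   class = "locus")
  replication_time(loc, scenario$replication, scenario$genome_map)
}

clamp_pos <- function(x, lo = 0.02, hi = 0.98) pmin(pmax(x, lo), hi)

#' Assemble a simulation scenario
#'
#' @param name scenario label.
#' @param genome_map a \code{\link{genome_map}}.
#' @param cycle a \code{\link{cell_cycle_model}}.
#' @param growth a \code{\link{growth_model}}.
#' @param replication a \code{\link{replication_model}}.
#' @param program position-program data.frame (one row per locus; see
#'   \code{\link{preset_scenario}}).
#' @param shrink polar-home shrink factor recorded for parS-deletion
#'   variants (already folded into \code{program}).
#' @param seg_transition_um cell elongation over which sisters travel to
#'   their new homes after splitting.
#' @return object of class \code{scenario}.
#' @export
scenario <- function(name, genome_map, cycle, growth, replication,
                     program, shrink = 1, seg_transition_um = 0.1) {
  stopifnot(is.data.frame(program),
            all(c("locus", "chromosome", "kb", "arm", "h_pre", "mode",
                  "midcell_age_min", "ramp_min", "cohesion_type",
                  "cohesion_par", "noise_sd", "home_old", "home_new")
                %in% names(program)),
            all(program$h_pre > 0 & program$h_pre < 1),
            all(program$noise_sd >= 0),
            shrink > 0, shrink <= 1, seg_transition_um > 0)
  structure(list(name = name, genome_map = genome_map, cycle = cycle,
                 growth = growth, replication = replication,
                 program = program, shrink = shrink,
                 seg_transition_um = seg_transition_um),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: %d loci, tau=%g min\n",
              x$name, nrow(x$program), x$cycle$tau_min))
  invisible(x)
}

# wild-type distance->home relation: linear interpolation in genomic
# path-fraction from the ori home to the ter home of the chromosome
wt_home_anchors <- list(I = c(ori = 0.8, ter = 0.1),
                        II = c(ori = 0.55, ter = 0.28))

wt_home <- function(kb, chromosome, genome) {
  chr <- genome$chromosomes[[chromosome]]
  a <- wt_home_anchors[[chromosome]]
  p <- arm_path(kb, chr)
  a["ori"] - (a["ori"] - a["ter"]) * min(p$dist_kb / p$arm_kb, 1)
}

# defaults for terminus-macrodomain loci: age of midcell recruitment and
# fraction of dividing cells with duplicated foci
ter_midcell_age <- c(ter_I = 47, L5_I = 41, R5_I = 42, ter_II = 44)
ter_div_fraction <- c(ter_I = 0.10, L5_I = 0.50, R5_I = 0.40,
                      ter_II = 0.25)

base_program <- function(panel, genome, noise_sd = 0.05) {
  rows <- lapply(panel, function(loc) {
    ter <- loc$arm == "ter"
    data.frame(
      locus = loc$name, chromosome = loc$chromosome,
      kb = loc$map_position_kb, arm = loc$arm,
      h_pre = unname(wt_home(loc$map_position_kb, loc$chromosome, genome)),
      mode = if (ter) "midcell_early" else "static",
      midcell_age_min = if (ter) {
        v <- ter_midcell_age[loc$name]; if (is.na(v)) 43 else unname(v)
      } else NA_real_,
      ramp_min = if (ter) 10 else NA_real_,
      cohesion_type = if (ter) "div_fraction" else "exp",
      cohesion_par = if (ter) {
        v <- ter_div_fraction[loc$name]; if (is.na(v)) 0.5 else unname(v)
      } else 5,
      noise_sd = noise_sd,
      home_old = NA_real_, home_new = NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Preset perturbation scenarios
#'
#' \describe{
#'   \item{\code{WT}}{homes interpolate linearly in genomic path-fraction
#'     from the ori home (0.8 on chromosome I, 0.55 on chromosome II) to
#'     the ter home (0.1 / 0.28); terminus-macrodomain loci are recruited
#'     to midcell late in the cycle and duplicate in only a fraction of
#'     dividing cells.}
#'   \item{\code{parS_displaced}}{the polar anchor moves to
#'     \code{parS_kb} on chromosome I: homes of non-terminus chromosome-I
#'     loci are re-computed from their genomic distance to the displaced
#'     parS using the wild-type distance-to-home relation; the terminus
#'     program is pinned unchanged.}
#'   \item{\code{delta_parS}}{no parS anchoring: chromosome-I homes
#'     shrink towards midcell so the ori home becomes 0.7, and
#'     chromosome-I positional noise is inflated.}
#'   \item{\code{delta_parS_ectopic_ori}}{as \code{delta_parS} plus an
#'     ectopic origin at \code{ectopic_kb}; chromosome-I homes are driven
#'     by replication time (earlier-replicating loci more polar) and the
#'     ori-region sisters segregate asymmetrically, one copy staying
#'     relatively polar.}
#' }
#'
#' @param name one of \code{"WT"}, \code{"parS_displaced"},
#'   \code{"delta_parS"}, \code{"delta_parS_ectopic_ori"}.
#' @param parS_kb position (kb) of the displaced parS cassette
#'   (\code{parS_displaced} only; e.g. 300, 490 or 650).
#' @param loci optional character vector restricting the locus panel.
#' @param genome a \code{\link{genome_map}}.
#' @param ectopic_kb position of the ectopic origin (kb) for
#'   \code{delta_parS_ectopic_ori}.
#' @return a \code{\link{scenario}}.
#' @export
preset_scenario <- function(name = c("WT", "parS_displaced", "delta_parS",
                                     "delta_parS_ectopic_ori"),
                            parS_kb = NULL, loci = NULL,
                            genome = vc_genome_map(), ectopic_kb = 651) {
  name <- match.arg(name)
  panel <- vc_locus_panel(genome)
  if (!is.null(loci)) {
    miss <- setdiff(loci, names(panel))
    if (length(miss)) stop("unknown loci: ", paste(miss, collapse = ", "))
    panel <- panel[loci]
  }
  cycle <- cell_cycle_model()
  growth <- growth_model()
  repl <- replication_model(genome, cycle)
  prog <- base_program(panel, genome)
  shrink <- 1
  label <- name

  if (name == "parS_displaced") {
    if (is.null(parS_kb)) stop("parS_displaced preset needs parS_kb")
    chrI <- genome$chromosomes[["I"]]
    a <- wt_home_anchors[["I"]]
    arm_kb <- (chrI$dif_kb - chrI$ori_kb) %% chrI$length_kb
    idx <- prog$chromosome == "I" & prog$arm != "ter"
    d <- circ_dist_kb(prog$kb[idx], parS_kb, chrI$length_kb)
    prog$h_pre[idx] <- pmax(a["ori"] - (a["ori"] - a["ter"]) *
                              pmin(d / arm_kb, 1), a["ter"])
    label <- sprintf("parS_displaced_%g", parS_kb)
  } else if (name == "delta_parS") {
    shrink <- (0.7 - 0.5) / (wt_home_anchors[["I"]]["ori"] - 0.5)
    idx <- prog$chromosome == "I" & prog$arm != "ter"
    prog$h_pre[idx] <- 0.5 + shrink * (prog$h_pre[idx] - 0.5)
    prog$noise_sd[prog$chromosome == "I"] <- 0.08
  } else if (name == "delta_parS_ectopic_ori") {
    repl <- replication_model(genome, cycle,
                              extra_origins = list(I = ectopic_kb))
    idx <- which(prog$chromosome == "I" & prog$arm != "ter")
    for (i in idx) {
      t_rep <- locus_t_rep(prog[i, , drop = FALSE],
                           list(replication = repl, genome_map = genome))
      prog$h_pre[i] <- 0.5 + 0.15 *
        max(0, 1 - (t_rep - cycle$B_min) / cycle$C_min)
      if (prog$arm[i] == "ori") {
        # residual (Par-independent) ori polarity and asymmetric
        # segregation: one copy stays relatively polar
        prog$h_pre[i] <- prog$h_pre[i] + 0.03
        prog$home_old[i] <- 0.88
        prog$home_new[i] <- 0.28
      }
    }
    prog$noise_sd[prog$chromosome == "I"] <- 0.08
  }
  scenario(label, genome, cycle, growth, repl, prog, shrink = shrink)
}

# locus_t_rep needs only $replication and $genome_map from the scenario;
# preset_scenario passes a bare list while building

#' Simulate a steady-state snapshot population
#'
#' Draws \code{n} cells with steady-state ages and Gaussian birth
#' lengths, grows them exponentially, samples per-locus focus states
#' (replication timing + cohesion delay) and noiseless positions, adds
#' localisation noise, and stores positions on a randomly flipped axis
#' (flip probability exactly 0.5) so that pole identity is unknown to
#' the analysis pipeline.  The true orientation and noiseless positions
#' are returned as ground truth.
#'
#' @param scenario a \code{\link{scenario}}.
#' @param n number of cells.
#' @param seed integer master seed (one RNG stream, fixed draw order:
#'   same seed, same dataset).
#' @return list with elements \code{dataset} (a
#'   \code{\link{strain_dataset}}) and \code{truth} (class
#'   \code{ground_truth}: per-cell ages, birth lengths and flips; per
#'   cell-locus replication/split ages, focus counts and noiseless
#'   true-frame positions).
#' @export
sample_population <- function(scenario, n, seed = 1) {
  stopifnot(inherits(scenario, "scenario"), n >= 1)
  set.seed(seed)
  tau <- scenario$cycle$tau_min
  ages <- steady_state_ages(n, tau)
  g <- scenario$growth
  Lb <- pmax(stats::rnorm(n, g$birth_length_mean_um, g$birth_length_sd_um),
             0.25 * g$birth_length_mean_um)
  L <- quantize_um(Lb * 2^(ages / tau))
  flip <- stats::runif(n) < 0.5
  ids <- sprintf("cell_%05d", seq_len(n))

  prog <- scenario$program
  foci_list <- vector("list", nrow(prog))
  truth_list <- vector("list", nrow(prog))
  for (k in seq_len(nrow(prog))) {
    row <- prog[k, , drop = FALSE]
    t_rep <- locus_t_rep(row, scenario)
    delay <- sample_cohesion(n, row, t_rep, scenario$cycle)
    t_split <- t_rep + delay
    split <- ages >= t_split
    pos_now <- pre_split_position(ages, row)
    s_at_split <- pre_split_position(t_split, row)
    homes <- row_homes(row)
    Ls <- Lb * 2^(t_split / tau)
    f <- pmin(pmax((L - Ls) / scenario$seg_transition_um, 0), 1)
    p1 <- ifelse(split, s_at_split + f * (homes[1] - s_at_split), pos_now)
    p2 <- ifelse(split, s_at_split + f * (homes[2] - s_at_split),
                 NA_real_)
    q1 <- clamp_pos(p1 + stats::rnorm(n, 0, row$noise_sd))
    q2 <- clamp_pos(p2 + stats::rnorm(n, 0, row$noise_sd))
    rel <- c(q1, ifelse(split, q2, NA_real_))
    cell <- c(ids, ids)
    keep <- !is.na(rel)
    Lk <- rep(L, 2)[keep]
    x <- pmin(pmax(quantize_um(rel[keep] * Lk), 0), Lk)
    fk <- rep(flip, 2)[keep]
    foci_list[[k]] <- data.frame(
      cell_id = cell[keep], channel = row$locus,
      position_um = ifelse(fk, Lk - x, x), stringsAsFactors = FALSE)
    truth_list[[k]] <- data.frame(
      cell_id = ids, locus = row$locus, t_rep_min = t_rep,
      t_split_min = t_split, n_foci = 1L + as.integer(split),
      pos1 = p1, pos2 = p2, stringsAsFactors = FALSE)
  }
  foci <- do.call(rbind, foci_list)
  # stable cell-major order
  foci <- foci[order(match(foci$cell_id, ids), foci$channel,
                     foci$position_um), , drop = FALSE]
  rownames(foci) <- NULL

  cells <- data.frame(cell_id = ids, length_um = L,
                      stringsAsFactors = FALSE)
  clmap <- lapply(seq_len(nrow(prog)), function(k)
    locus(prog$locus[k], prog$chromosome[k], prog$kb[k],
          scenario$genome_map))
  names(clmap) <- prog$locus
  ds <- strain_dataset(paste0("sim_", scenario$name), cells, foci,
                       channel_locus_map = clmap,
                       scenario = scenario$name)
  truth <- structure(list(
    scenario = scenario$name, seed = seed,
    cells = data.frame(cell_id = ids, age_min = ages,
                       birth_length_um = Lb, length_um = L,
                       flipped = flip, stringsAsFactors = FALSE),
    loci = do.call(rbind, truth_list)), class = "ground_truth")
  list(dataset = ds, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> scenario %s, %d cells, %d loci\n",
              x$scenario, nrow(x$cells),
              length(unique(x$loci$locus))))
  invisible(x)
}

#' Noiseless oriented dataset from simulation ground truth
#'
#' Rebuilds a \code{\link{strain_dataset}} from the ground truth of a
#' simulation: noiseless positions in the true new-pole frame, every
#' cell marked oriented.  Used as the reference when checking that the
#' windowed statistics recover the positional program.
#'
#' @param truth a \code{ground_truth} from
#'   \code{\link{sample_population}}.
#' @return a \code{strain_dataset}.
#' @export
truth_dataset <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  tl <- truth$loci
  L <- truth$cells$length_um[match(tl$cell_id, truth$cells$cell_id)]
  two <- tl$n_foci == 2L
  foci <- rbind(
    data.frame(cell_id = tl$cell_id, channel = tl$locus,
               position_um = clamp_pos(tl$pos1) * L,
               stringsAsFactors = FALSE),
    data.frame(cell_id = tl$cell_id[two], channel = tl$locus[two],
               position_um = (clamp_pos(tl$pos2) * L)[two],
               stringsAsFactors = FALSE))
  cells <- data.frame(cell_id = truth$cells$cell_id,
                      length_um = truth$cells$length_um,
                      orientation = "oriented", polarity_flip = FALSE,
                      stringsAsFactors = FALSE)
  strain_dataset(paste0("truth_", truth$scenario), cells, foci,
                 scenario = truth$scenario)
}
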