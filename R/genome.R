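#' Genome map for a two-chromosome bacterium
#'
#' Describes, per chromosome, the circular map coordinates that the
#' positional model needs: total length, replication origin (\emph{oriC}),
#' replication terminus / dimer-resolution site (\emph{dif}), the
#' centromere-like \emph{parS} sites, the \emph{matS}-organised terminus
#' macrodomain, and (optionally) an ectopic replication origin.
#'
#' @param chromosomes named list (names \code{"I"}, \code{"II"}) of lists
#'   with elements \code{length_kb}, \code{ori_kb}, \code{dif_kb},
#'   \code{parS_kb} (numeric vector), \code{matS_domain_kb} (length-2
#'   interval) and optionally \code{ectopic_ori_kb}.
#' @return An object of class \code{genome_map}.
#' @export
genome_map <- function(chromosomes) {
  stopifnot(is.list(chromosomes), length(chromosomes) >= 1,
            !is.null(names(chromosomes)))
  for (nm in names(chromosomes)) {
    chr <- chromosomes[[nm]]
    stopifnot(chr$length_kb > 0,
              chr$ori_kb >= 0, chr$ori_kb < chr$length_kb,
              chr$dif_kb >= 0, chr$dif_kb < chr$length_kb)
    m <- chr$matS_domain_kb
    if (!is.null(m)) {
      stopifnot(length(m) == 2L, m[1] <= chr$dif_kb, chr$dif_kb <= m[2])
    }
  }
  structure(list(chromosomes = chromosomes), class = "genome_map")
}

#' Default Vibrio cholerae genome map
#'
#' Chromosome I (2961 kb) with oriC1 at 0 and dif1 opposite, three natural
#' parS1 sites near the origin, and a terminus macrodomain covering the
#' matS-site region; chromosome II (1072 kb) with oriC2 at 0 and dif2
#' opposite.  Coordinates increase along the left replichore from ori to
#' dif; the right replichore runs from \code{length_kb} down to dif.
#'
#' @return A \code{genome_map}.
#' @export
vc_genome_map <- function() {
  genome_map(list(
    I = list(length_kb = 2961, ori_kb = 0, dif_kb = 1480.5,
             parS_kb = 65, matS_domain_kb = c(1250, 1710)),
    II = list(length_kb = 1072, ori_kb = 0, dif_kb = 536,
              parS_kb = 10, matS_domain_kb = c(470, 600))
  ))
}

#' Define a tagged genomic locus
#'
#' @param name locus identifier (e.g. \code{"ori_I"}, \code{"L3_I"}).
#' @param chromosome \code{"I"} or \code{"II"}.
#' @param map_position_kb coordinate on the circular map, in kb.
#' @param genome a \code{genome_map}; used to derive the arm and to check
#'   the coordinate.
#' @return An object of class \code{locus} with fields \code{name},
#'   \code{chromosome}, \code{map_position_kb} and \code{arm} (one of
#'   \code{"ori"}, \code{"left"}, \code{"right"}, \code{"ter"}).
#' @export
locus <- function(name, chromosome, map_position_kb, genome = vc_genome_map()) {
  chr <- genome$chromosomes[[chromosome]]
  if (is.null(chr)) stop("unknown chromosome: ", chromosome)
  if (map_position_kb < 0 || map_position_kb >= chr$length_kb)
    stop("locus ", name, " at ", map_position_kb,
         " kb outside chromosome ", chromosome)
  arm <- classify_arm(map_position_kb, chr)
  structure(list(name = name, chromosome = chromosome,
                 map_position_kb = map_position_kb, arm = arm),
            class = "locus")
}

# arm classification: terminus macrodomain wins, then proximity to ori,
# then left (ascending kb from ori) vs right replichore
classify_arm <- function(kb, chr, ori_margin_kb = 50) {
  m <- chr$matS_domain_kb
  if (!is.null(m) && kb >= m[1] && kb <= m[2]) return("ter")
  d <- circ_dist_kb(kb, chr$ori_kb, chr$length_kb)
  if (d <= ori_margin_kb) return("ori")
  # path position relative to ori along increasing coordinates
  fwd <- (kb - chr$ori_kb) %% chr$length_kb
  fwd_to_dif <- (chr$dif_kb - chr$ori_kb) %% chr$length_kb
  if (fwd <= fwd_to_dif) "left" else "right"
}

# shortest distance between two coordinates on a circular map
circ_dist_kb <- function(a, b, length_kb) {
  d <- abs(a - b) %% length_kb
  pmin(d, length_kb - d)
}

# genomic path distance from a locus to ori along its own replichore,
# and the kb length of that replichore
arm_path <- function(kb, chr) {
  fwd <- (kb - chr$ori_kb) %% chr$length_kb
  fwd_to_dif <- (chr$dif_kb - chr$ori_kb) %% chr$length_kb
  if (fwd <= fwd_to_dif) {
    list(dist_kb = fwd, arm_kb = fwd_to_dif)
  } else {
    list(dist_kb = chr$length_kb - fwd,
         arm_kb = chr$length_kb - fwd_to_dif)
  }
}

#' Reference locus panel for the wild-type strains
#'
#' Twelve chromosome-I loci (ori, five left-replichore and five
#' right-replichore tags, the terminus) and seven chromosome-II loci,
#' ordered \emph{ori} to \emph{ter} along each arm.
#'
#' @param genome a \code{genome_map}.
#' @return Named list of \code{locus} objects.
#' @export
vc_locus_panel <- function(genome = vc_genome_map()) {
  def <- list(
    ori_I = c("I", 0),    L1_I = c("I", 220),  L2_I = c("I", 480),
    L3_I  = c("I", 650),  L4_I = c("I", 1000), L5_I = c("I", 1280),
    ter_I = c("I", 1480),
    R1_I  = c("I", 2740), R2_I = c("I", 2530), R3_I = c("I", 2170),
    R4_I  = c("I", 1960), R5_I = c("I", 1680),
    ori_II = c("II", 0),  L1_II = c("II", 150), L2_II = c("II", 300),
    ter_II = c("II", 536),
    R1_II = c("II", 1020), R2_II = c("II", 950), R3_II = c("II", 850)
  )
  out <- lapply(names(def), function(nm) {
    locus(nm, def[[nm]][1], as.numeric(def[[nm]][2]), genome)
  })
  names(out) <- names(def)
  out
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("<locus> %s  chr%s @ %.0f kb  arm=%s\n",
              x$name, x$chromosome, x$map_position_kb, x$arm))
  invisible(x)
}

#' @export
print.genome_map <- function(x, ...) {
  for (nm in names(x$chromosomes)) {
    chr <- x$chromosomes[[nm]]
    cat(sprintf("chr%s: %g kb, ori %g, dif %g\n",
                nm, chr$length_kb, chr$ori_kb, chr$dif_kb))
  }
  invisible(x)
}
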