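#' Simulation configuration for a synthetic neo-sex-chromosome cohort
#'
#' Describes the stated world the generator emulates: two sister species that
#' split `species_split_kya` ago; a pool of neo-X haplotypes carrying standing
#' diversity `theta`; and neo-Y lineages that are recombinant mosaics of those
#' neo-X haplotypes plus an outgroup-derived block near the centromere. Each
#' neo-Y group stops recombining at its own `recomb_stop_kya`, after which the
#' group's Ys descend clonally from one founder and accumulate private
#' substitutions and indels at rates `mu` and `indel_rate`.
#'
#' Time is measured in kyr with a fixed per-kyr substitution rate (no
#' generation-time conversion). The neo-X pool follows a star genealogy of
#' depth `theta / (2 * mu)` kyr, which must exceed every group's stop time so
#' that a Y founder is a copy of a then-extant neo-X lineage.
#'
#' @param chromosome_length Chromosome length in bp.
#' @param n_genes Number of genes (single-CDS, non-overlapping).
#' @param gene_length CDS length in bp (rounded down to a codon multiple).
#' @param mu Substitution rate per bp per kyr.
#' @param indel_rate Indel rate per bp per kyr (post-recombination neo-Y only).
#' @param theta Expected pairwise diversity among neo-X haplotypes (per bp).
#' @param species_split_kya Species split time in kyr (default 250).
#' @param y_groups List of groups, each `list(name, n_strains, recomb_stop_kya,
#'   breakpoints)`; `breakpoints` are strictly increasing bp positions in
#'   `(0, chromosome_length)` at which the founder mosaic switches donor.
#' @param nasuta_block Two-element bp vector `(start, end)` (0-based half-open)
#'   of the outgroup-derived block carried by every neo-Y.
#' @param n_neoX Number of neo-X haplotypes in the pool (>= 2).
#' @param n_outgroup Number of outgroup (Chr.3) strains.
#' @param outgroup_depth_kya Star-genealogy depth of the outgroup strains, kyr.
#' @param ase_ratios Per-gene true neo-X:neo-Y expression ratios (recycled to
#'   `n_genes`; default 1, i.e. no allelic bias).
#' @param dna_depth,rna_depth Mean read count per gene per allele.
#' @param tissue_profile List with `tissues` (names, >= 2), `frac_biased`,
#'   `biased_tissue` (NULL = random per gene), `noise_sd` (lognormal sd).
#' @param inbreeding Probability a strain's female is homozygous for its neo-X
#'   haplotype (residual heterozygosity exercises missing-data handling).
#' @param mean_depth,lowqual_frac Sequencing depth model for emitted genotypes.
#' @param seed Integer seed; a fixed seed makes all outputs byte-identical.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(chromosome_length = 2e6,
                       n_genes = 40,
                       gene_length = 900,
                       mu = 4e-6,
                       indel_rate = 4e-7,
                       theta = 2e-3,
                       species_split_kya = 250,
                       y_groups = list(
                         list(name = "Y1", n_strains = 3, recomb_stop_kya = 106.8,
                              breakpoints = c(4e5, 16e5)),
                         list(name = "Y2", n_strains = 2, recomb_stop_kya = 89.6,
                              breakpoints = c(4e5, 12e5)),
                         list(name = "Y3", n_strains = 3, recomb_stop_kya = 135.2,
                              breakpoints = c(4e5, 18e5))
                       ),
                       nasuta_block = c(0, 2e5),
                       n_neoX = 6,
                       n_outgroup = 2,
                       outgroup_depth_kya = 200,
                       ase_ratios = NULL,
                       dna_depth = 200,
                       rna_depth = 200,
                       tissue_profile = list(
                         tissues = c("testis", "ovary", "head", "gut",
                                     "carcass", "accessory_gland"),
                         frac_biased = 0.3, biased_tissue = NULL,
                         noise_sd = 0.1),
                       inbreeding = 0.7,
                       mean_depth = 30,
                       lowqual_frac = 0.01,
                       seed = 1L) {
  cfg <- list(chromosome_length = as.integer(chromosome_length),
              n_genes = as.integer(n_genes), gene_length = as.integer(gene_length),
              mu = mu, indel_rate = indel_rate, theta = theta,
              species_split_kya = species_split_kya, y_groups = y_groups,
              nasuta_block = nasuta_block, n_neoX = as.integer(n_neoX),
              n_outgroup = as.integer(n_outgroup),
              outgroup_depth_kya = outgroup_depth_kya,
              ase_ratios = ase_ratios, dna_depth = dna_depth,
              rna_depth = rna_depth, tissue_profile = tissue_profile,
              inbreeding = inbreeding, mean_depth = mean_depth,
              lowqual_frac = lowqual_frac, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  L <- cfg$chromosome_length
  if (L <= 0) stop("zero-length chromosome")
  if (any(c(cfg$mu, cfg$indel_rate, cfg$theta) < 0)) stop("rates must be >= 0")
  if (cfg$n_neoX < 2) stop("n_neoX must be >= 2 for diversity estimates")
  if (length(cfg$nasuta_block) != 2 ||
      cfg$nasuta_block[1] < 0 || cfg$nasuta_block[2] > L ||
      cfg$nasuta_block[1] >= cfg$nasuta_block[2])
    stop("nasuta_block outside chromosome")
  for (g in cfg$y_groups) {
    if (g$n_strains < 1) stop("group with 0 strains: ", g$name)
    if (g$recomb_stop_kya >= cfg$species_split_kya)
      stop("recomb_stop_kya must be < species_split_kya for group ", g$name)
    bp <- g$breakpoints
    if (length(bp) && (any(diff(bp) <= 0) || any(bp <= 0) || any(bp >= L)))
      stop("breakpoints must be strictly increasing within (0, L): ", g$name)
  }
  if (cfg$outgroup_depth_kya >= cfg$species_split_kya)
    stop("outgroup_depth_kya must be < species_split_kya")
  if (cfg$mu > 0) {
    t_x <- cfg$theta / (2 * cfg$mu)
    stops <- vapply(cfg$y_groups, `[[`, numeric(1), "recomb_stop_kya")
    if (any(stops >= t_x))
      stop("theta/(2*mu) = ", signif(t_x, 4),
           " kyr must exceed every recomb_stop_kya (neo-X pool must predate ",
           "the Y founders)")
    if (any(stops >= cfg$outgroup_depth_kya))
      stop("outgroup_depth_kya must exceed every recomb_stop_kya so the ",
           "outgroup-derived block coalesces within the outgroup crown")
  }
  if (cfg$n_genes > 0 && cfg$n_genes * cfg$gene_length > L)
    stop("genes do not fit on the chromosome")
  if (length(cfg$tissue_profile$tissues) < 2) stop("need >= 2 tissues")
  if (!is.null(cfg$ase_ratios) && any(cfg$ase_ratios <= 0))
    stop("ase_ratios must be > 0")
  invisible(cfg)
}
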