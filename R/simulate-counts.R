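#' Simulate per-gene allele-specific DNA and RNA read counts
#'
#' Counts are Poisson per allele. DNA counts have a 1:1 expected allelic
#' ratio (mean `dna_depth` per allele). RNA counts follow each gene's true
#' neo-X:neo-Y ratio `r`, with allele means `rna_depth * 2r/(1+r)` (neo-X)
#' and `rna_depth * 2/(1+r)` (neo-Y), so the total mean per gene is
#' `2 * rna_depth` regardless of the ratio — mirroring a coverage-ratio read
#' simulation (e.g. 10x:5x for a 2-fold bias).
#'
#' @param config A [sim_config()] object; `ase_ratios` (recycled to
#'   `n_genes`) sets the per-gene true ratios, `dna_depth`/`rna_depth` the
#'   mean per-allele counts, and `seed` the RNG seed.
#' @return List with `dna` and `rna` data.frames (`gene`, `x`, `y`), the
#'   combined `records` table (`gene`, `rna_x`, `rna_y`, `dna_x`, `dna_y`),
#'   and `truth` (the per-gene ratios).
#' @export
simulate_allele_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (!is.null(cfg$ase_ratios) && any(cfg$ase_ratios <= 0))
    stop("ase_ratios must be > 0")
  if (cfg$dna_depth <= 0 || cfg$rna_depth <= 0) stop("depths must be > 0")
  n <- max(cfg$n_genes, length(cfg$ase_ratios %||% 1))
  r <- rep(cfg$ase_ratios %||% 1, length.out = n)
  set.seed(derive_seed(cfg$seed, 2L))
  genes <- sprintf("gene%04d", seq_len(n))
  dna <- data.frame(gene = genes,
                    x = stats::rpois(n, cfg$dna_depth),
                    y = stats::rpois(n, cfg$dna_depth))
  rna <- data.frame(gene = genes,
                    x = stats::rpois(n, cfg$rna_depth * 2 * r / (1 + r)),
                    y = stats::rpois(n, cfg$rna_depth * 2 / (1 + r)))
  records <- data.frame(gene = genes, rna_x = rna$x, rna_y = rna$y,
                        dna_x = dna$x, dna_y = dna$y)
  list(dna = dna, rna = rna, records = records, truth = list(ratios = r))
}

#' Simulate a genes-by-tissues expression matrix with known bias labels
#'
#' A configured fraction of genes is tissue-biased: expression concentrated
#' in one top tissue (level 100) with a secondary tissue at 30 and zero
#' elsewhere, giving tau well above 0.5. Unbiased genes are uniform (level
#' 50). Multiplicative lognormal noise with sd `noise_sd` is applied; at
#' `noise_sd = 0` the truth labels are recovered exactly by [compute_tau()].
#'
#' @param config A [sim_config()] object (`tissue_profile`, `n_genes`, `seed`).
#' @return List with `expr` (matrix genes x tissues, RPKM-like), `truth`
#'   (data.frame: gene, biased, top_tissue).
#' @export
simulate_tissue_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  tp <- cfg$tissue_profile
  tissues <- tp$tissues
  if (length(tissues) < 2) stop("need >= 2 tissues")
  set.seed(derive_seed(cfg$seed, 3L))
  n <- cfg$n_genes
  genes <- sprintf("gene%03d", seq_len(n))
  biased <- seq_len(n) <= round(n * tp$frac_biased)
  biased <- sample(biased)   # scatter labels over gene ids
  top <- ifelse(biased,
                if (is.null(tp$biased_tissue))
                  sample(tissues, n, replace = TRUE) else tp$biased_tissue,
                NA_character_)
  expr <- matrix(50, nrow = n, ncol = length(tissues),
                 dimnames = list(genes, tissues))
  for (i in which(biased)) {
    expr[i, ] <- 0
    expr[i, top[i]] <- 100
    second <- sample(setdiff(tissues, top[i]), 1)
    expr[i, second] <- 30
  }
  if (tp$noise_sd > 0)
    expr <- expr * matrix(stats::rlnorm(length(expr), 0, tp$noise_sd),
                          nrow = n)
  list(expr = expr,
       truth = data.frame(gene = genes, biased = biased, top_tissue = top,
                          stringsAsFactors = FALSE))
}
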