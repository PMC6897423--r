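#' Simulate a synthetic neo-sex-chromosome cohort
#'
#' Generates a diploid genotype table, a reference sequence, a gene
#' annotation, haploid truth haplotypes, and a truth set with the structure
#' the downstream analysis assumes: a pool of neo-X haplotypes with standing
#' diversity (star genealogy of depth `theta/(2*mu)` kyr), an outgroup
#' lineage diverged at the species split, and neo-Y groups that are
#' recombinant mosaics of neo-X donors (plus an outgroup-derived block near
#' the centromere) frozen at each group's recombination-stop time, after
#' which the group's Ys descend clonally from one founder, accumulating
#' Poisson(`mu * L * stop_kya`) private substitutions and
#' Poisson(`indel_rate * L * stop_kya`) private indels.
#'
#' Diploid encoding mirrors female-assembly mapping: females are
#' neo-X/neo-X, males are neo-X/neo-Y (the neo-Y allele is one allele of a
#' heterozygous call), outgroup strains are Chr.3/Chr.3 homozygotes.
#'
#' Substitutions are placed under an infinite-sites draw (a global sample of
#' positions without replacement), so every simulated variant belongs to
#' exactly one truth category.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `neoy_cohort`: a list with `config`, `chrom`,
#'   `reference` (character vector of bases), `genes` (data.frame of CDS
#'   spans), `haplotypes` (`pos`, allele matrix `mat` with one column per
#'   haploid tip, `classes` mapping tip to `neoX`/`chr3`/Y-group),
#'   `genotypes` (long data.table: chrom, pos, ref, sample, a1, a2, dp, gq),
#'   `indel_genotypes`, `samples`, and `truth` (segments, breakpoints, stop
#'   times, group-fixed variants with effect classes, allelic ratios).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  L <- cfg$chromosome_length
  Ts <- cfg$species_split_kya
  t_x <- if (cfg$mu > 0) cfg$theta / (2 * cfg$mu) else Ts / 2
  t_o <- cfg$outgroup_depth_kya

  ref <- sample(DNA_BASES, L, replace = TRUE)
  genes <- place_genes(cfg, L)
  ref <- make_orfs(ref, genes)   # stop-free CDS on the annotated strand

  ## --- substitution sets (infinite sites: one global position draw) -------
  n_stem <- stats::rpois(1, cfg$mu * L * max(0, Ts - t_x))
  n_P <- stats::rpois(cfg$n_neoX, cfg$mu * L * t_x)
  n_Oshared <- stats::rpois(1, cfg$mu * L * max(0, Ts - t_o))
  n_Opriv <- stats::rpois(cfg$n_outgroup, cfg$mu * L * t_o)
  # two unsampled ancestral donor lineages: the original fusion Y haplotype
  # (a neo-X pool lineage) and the outgroup-derived block haplotype; the
  # latter branches off the first outgroup strain lineage midway between the
  # oldest recombination stop, so block windows place the neo-Ys inside the
  # outgroup crown (species sorting fails there, as it should)
  stops <- vapply(cfg$y_groups, `[[`, numeric(1), "recomb_stop_kya")
  max_stop <- if (length(stops)) max(stops) else 0
  t_n <- max_stop + 0.5 * (t_o - max_stop)
  n_ancY <- stats::rpois(1, cfg$mu * L * t_x)
  n_ancN <- stats::rpois(1, cfg$mu * L * t_n)
  n_C <- stats::rpois(length(cfg$y_groups), cfg$mu * L * stops)
  total <- n_stem + sum(n_P) + n_Oshared + sum(n_Opriv) + n_ancY + n_ancN + sum(n_C)
  if (total > L) stop("mutation load exceeds chromosome length; shorten times or rates")
  all_pos <- sample.int(L, total)
  all_alt <- random_alt(ref[all_pos])
  take <- local({i <- 0L; function(n) {idx <- seq_len(n) + i; i <<- i + n; idx}})
  sub_set <- function(n, tmin = NULL, tmax = NULL) {
    idx <- take(n)
    data.frame(pos = all_pos[idx], alt = all_alt[idx],
               time = if (is.null(tmin)) rep(NA_real_, n) else stats::runif(n, tmin, tmax))
  }
  stem <- sub_set(n_stem)
  P <- lapply(seq_len(cfg$n_neoX), function(j) sub_set(n_P[j], 0, t_x))
  Oshared <- sub_set(n_Oshared, t_o, Ts)
  Opriv <- lapply(seq_len(cfg$n_outgroup), function(k) sub_set(n_Opriv[k], 0, t_o))
  ancY <- sub_set(n_ancY, 0, t_x)
  ancN <- sub_set(n_ancN, 0, t_n)
  Cg <- lapply(seq_along(cfg$y_groups), function(g) sub_set(n_C[g]))

  ## --- founder mosaics -----------------------------------------------------
  blk <- cfg$nasuta_block
  group_names <- vapply(cfg$y_groups, `[[`, character(1), "name")
  seg_list <- list(); y_var_list <- list()
  for (g in seq_along(cfg$y_groups)) {
    grp <- cfg$y_groups[[g]]
    bnd <- sort(unique(c(0, grp$breakpoints, blk, L)))
    segs <- data.frame(start = bnd[-length(bnd)], end = bnd[-1])
    in_blk <- segs$start >= blk[1] & segs$end <= blk[2]
    # donors: centromere-proximal block descends from the shared
    # outgroup-derived haplotype (ancN); the telomeric-end segment retains
    # the shared original fusion haplotype (ancY); middle segments take
    # per-group sampled neo-X donors
    donor_idx <- sample.int(cfg$n_neoX, nrow(segs), replace = TRUE)
    segs$donor <- paste0("neoX_", donor_idx)
    segs$donor[in_blk] <- "ancN"
    segs$donor[nrow(segs)] <- if (in_blk[nrow(segs)]) "ancN" else "ancY"
    segs$group <- grp$name
    seg_list[[g]] <- segs
    t_g <- grp$recomb_stop_kya
    pieces <- lapply(seq_len(nrow(segs)), function(s) {
      lo <- segs$start[s]; hi <- segs$end[s]   # 0-based half-open
      inside <- function(df) df[df$pos > lo & df$pos <= hi, c("pos", "alt")]
      switch(substr(segs$donor[s], 1, 4),
        ancN = rbind(inside(Oshared[Oshared$time > t_g, ]),
                     inside(Opriv[[1]][Opriv[[1]]$time > t_n, ]),
                     inside(ancN[ancN$time > t_g, ])),
        ancY = rbind(inside(stem), inside(ancY[ancY$time > t_g, ])),
        rbind(inside(stem),
              inside(P[[donor_idx[s]]][P[[donor_idx[s]]]$time > t_g, ])))
    })
    y_var_list[[g]] <- rbind(do.call(rbind, pieces), Cg[[g]][, c("pos", "alt")])
  }
  segments <- do.call(rbind, seg_list)

  ## --- haploid allele matrix ----------------------------------------------
  hap_vars <- c(
    stats::setNames(lapply(P, function(p) rbind(stem[, c("pos", "alt")], p[, c("pos", "alt")])),
                    paste0("neoX_", seq_len(cfg$n_neoX))),
    stats::setNames(lapply(seq_len(cfg$n_outgroup), function(k)
      rbind(Oshared[, c("pos", "alt")], Opriv[[k]][, c("pos", "alt")])),
      paste0("out_", seq_len(cfg$n_outgroup))),
    stats::setNames(y_var_list, paste0("Yfounder_", group_names))
  )
  pos_all <- sort(unique(unlist(lapply(hap_vars, `[[`, "pos"))))
  founder_mat <- matrix(ref[pos_all], nrow = length(pos_all), ncol = length(hap_vars),
                        dimnames = list(NULL, names(hap_vars)))
  for (nm in names(hap_vars)) {
    v <- hap_vars[[nm]]
    founder_mat[match(v$pos, pos_all), nm] <- v$alt
  }

  # expand clonal founders to per-strain tips
  tip_names <- character(0); tip_source <- character(0); tip_class <- character(0)
  for (j in seq_len(cfg$n_neoX)) {
    tip_names <- c(tip_names, paste0("neoX_", j))
    tip_source <- c(tip_source, paste0("neoX_", j)); tip_class <- c(tip_class, "neoX")
  }
  for (g in seq_along(cfg$y_groups)) {
    grp <- cfg$y_groups[[g]]
    for (i in seq_len(grp$n_strains)) {
      tip_names <- c(tip_names, paste0(grp$name, "_", i))
      tip_source <- c(tip_source, paste0("Yfounder_", grp$name))
      tip_class <- c(tip_class, grp$name)
    }
  }
  for (k in seq_len(cfg$n_outgroup)) {
    tip_names <- c(tip_names, paste0("out_", k))
    tip_source <- c(tip_source, paste0("out_", k)); tip_class <- c(tip_class, "chr3")
  }
  hap_mat <- founder_mat[, tip_source, drop = FALSE]
  colnames(hap_mat) <- tip_names
  classes <- stats::setNames(tip_class, tip_names)

  ## --- group-fixed indels --------------------------------------------------
  indel_truth <- lapply(seq_along(cfg$y_groups), function(g) {
    t_g <- stops[g]
    n <- stats::rpois(1, cfg$indel_rate * L * t_g)
    if (n == 0) return(NULL)
    pos <- sort(sample(setdiff(seq_len(L - 7L), all_pos), n))
    len <- sample(1:6, n, replace = TRUE, prob = c(.40, .25, .15, .10, .06, .04))
    type <- sample(c("del", "ins"), n, replace = TRUE)
    ins_seq <- vapply(len, function(k) paste(sample(DNA_BASES, k, replace = TRUE),
                                             collapse = ""), character(1))
    refal <- ifelse(type == "del",
                    vapply(seq_len(n), function(i)
                      chars_to_string(ref[pos[i]:(pos[i] + len[i])]), character(1)),
                    ref[pos])
    altal <- ifelse(type == "del", ref[pos], paste0(ref[pos], ins_seq))
    data.frame(group = group_names[g], pos = pos, len = len, type = type,
               ref = refal, alt = altal, stringsAsFactors = FALSE)
  })
  indel_truth <- do.call(rbind, indel_truth[!vapply(indel_truth, is.null, logical(1))])
  if (is.null(indel_truth))
    indel_truth <- data.frame(group = character(0), pos = integer(0), len = integer(0),
                              type = character(0), ref = character(0), alt = character(0))

  ## --- truth effect classes (generator-side, direct codon arithmetic) -----
  fixed_snps <- do.call(rbind, lapply(seq_along(cfg$y_groups), function(g)
    if (nrow(Cg[[g]])) data.frame(group = group_names[g], pos = Cg[[g]]$pos,
                                  ref = ref[Cg[[g]]$pos], alt = Cg[[g]]$alt)))
  if (is.null(fixed_snps))
    fixed_snps <- data.frame(group = character(0), pos = integer(0),
                             ref = character(0), alt = character(0))
  fixed_snps$effect <- truth_snp_effect(fixed_snps$pos, fixed_snps$alt, genes, ref)
  indel_truth$effect <- truth_indel_effect(indel_truth$pos, indel_truth$len,
                                           indel_truth$type, genes)

  ## --- diploid samples -----------------------------------------------------
  strain_tbl <- list(); geno_rows <- list(); indel_rows <- list()
  n_sites <- length(pos_all)
  add_sample <- function(name, h1, h2, strain, sex, class) {
    strain_tbl[[length(strain_tbl) + 1L]] <<- data.frame(
      sample = name, strain = strain, sex = sex, class = class)
    dp <- stats::rpois(n_sites, cfg$mean_depth)
    gq <- rep(99L, n_sites)
    nlow <- stats::rbinom(1, n_sites, cfg$lowqual_frac)
    if (nlow > 0) {
      idx <- sample.int(n_sites, nlow)
      half <- idx[seq_len(ceiling(nlow / 2))]
      dp[half] <- sample(0:4, length(half), replace = TRUE)
      gq[setdiff(idx, half)] <- sample(0:19, length(setdiff(idx, half)), replace = TRUE)
    }
    geno_rows[[length(geno_rows) + 1L]] <<- data.table::data.table(
      chrom = "neoChr", pos = pos_all, ref = ref[pos_all], sample = name,
      a1 = hap_mat[, h1], a2 = hap_mat[, h2], dp = dp, gq = gq)
  }
  for (g in seq_along(cfg$y_groups)) {
    grp <- cfg$y_groups[[g]]
    for (i in seq_len(grp$n_strains)) {
      strain <- paste0(grp$name, "_", i)
      xa <- paste0("neoX_", sample.int(cfg$n_neoX, 1))
      xb <- if (stats::runif(1) < cfg$inbreeding) xa
            else paste0("neoX_", sample.int(cfg$n_neoX, 1))
      add_sample(paste0("female_", strain), xa, xb, strain, "female", grp$name)
      add_sample(paste0("male_", strain), xa, strain, strain, "male", grp$name)
      gi <- indel_truth[indel_truth$group == grp$name, , drop = FALSE]
      if (nrow(gi)) {
        hom <- stats::runif(nrow(gi)) < 0.1  # caller quirk: male-specific hom indels
        indel_rows[[length(indel_rows) + 1L]] <- data.table::data.table(
          chrom = "neoChr", pos = gi$pos, ref = gi$ref, alt = gi$alt,
          sample = paste0("male_", strain), strain = strain,
          a1 = ifelse(hom, gi$alt, gi$ref), a2 = gi$alt,
          dp = stats::rpois(nrow(gi), cfg$mean_depth), gq = 99L)
        indel_rows[[length(indel_rows) + 1L]] <- data.table::data.table(
          chrom = "neoChr", pos = gi$pos, ref = gi$ref, alt = gi$alt,
          sample = paste0("female_", strain), strain = strain,
          a1 = gi$ref, a2 = gi$ref,
          dp = stats::rpois(nrow(gi), cfg$mean_depth), gq = 99L)
      }
    }
  }
  for (k in seq_len(cfg$n_outgroup)) {
    nm <- paste0("out_", k)
    add_sample(paste0("sample_", nm), nm, nm, nm, "female", "chr3")
  }

  ratios <- rep(cfg$ase_ratios %||% 1, length.out = max(cfg$n_genes, 1L))
  segments_per_sample <- do.call(rbind, lapply(seq_along(cfg$y_groups), function(g) {
    grp <- cfg$y_groups[[g]]
    do.call(rbind, lapply(seq_len(grp$n_strains), function(i) {
      s <- seg_list[[g]]; s$sample <- paste0(grp$name, "_", i); s
    }))
  }))

  structure(list(
    config = cfg, chrom = "neoChr", reference = ref, genes = genes,
    haplotypes = list(pos = pos_all, mat = hap_mat, classes = classes, L = L),
    genotypes = data.table::rbindlist(geno_rows),
    indel_genotypes = if (length(indel_rows)) data.table::rbindlist(indel_rows)
                      else data.table::data.table(),
    samples = do.call(rbind, strain_tbl),
    truth = list(
      segments = segments_per_sample,
      breakpoints = lapply(stats::setNames(cfg$y_groups, group_names),
                           `[[`, "breakpoints"),
      stop_kya = stats::setNames(stops, group_names),
      group_fixed_snps = fixed_snps,
      group_fixed_indels = indel_truth,
      ase_ratios = ratios,
      neoX_depth_kya = t_x)
  ), class = "neoy_cohort")
}

random_alt <- function(refbase) {
  n <- length(refbase)
  if (n == 0) return(character(0))
  shift <- sample.int(3, n, replace = TRUE)
  idx <- (match(refbase, DNA_BASES) - 1L + shift) %% 4L + 1L
  DNA_BASES[idx]
}

place_genes <- function(cfg, L) {
  n <- cfg$n_genes
  if (n == 0)
    return(data.frame(gene = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  glen <- (cfg$gene_length %/% 3L) * 3L
  spacing <- L %/% n
  offset <- max(1L, (spacing - glen) %/% 2L)
  start <- (seq_len(n) - 1L) * spacing + offset
  data.frame(gene = sprintf("gene%03d", seq_len(n)),
             start = start, end = start + glen - 1L,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# rewrite each annotated CDS with codons drawn from the 61 sense codons, so
# annotated genes are valid ORFs (random sequence would carry internal stops)
make_orfs <- function(ref, genes) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  for (i in seq_len(nrow(genes))) {
    n_codon <- (genes$end[i] - genes$start[i] + 1L) %/% 3L
    cds <- paste(sample(sense, n_codon, replace = TRUE), collapse = "")
    if (genes$strand[i] == "-") cds <- revcomp(cds)
    ref[genes$start[i]:genes$end[i]] <- strsplit(cds, "")[[1]]
  }
  ref
}

# effect of a single SNP applied to the reference CDS (generator-side truth)
truth_snp_effect <- function(pos, alt, genes, ref, flank = 500L) {
  if (length(pos) == 0) return(character(0))
  gc <- Biostrings::GENETIC_CODE
  vapply(seq_along(pos), function(i) {
    p <- pos[i]
    hit <- which(genes$start <= p & genes$end >= p)
    if (length(hit) == 0) {
      near <- any(genes$start - flank <= p & genes$end + flank >= p)
      return(if (near) "near_gene_500bp" else "intergenic")
    }
    g <- genes[hit[1], ]
    if (g$strand == "+") {
      off <- p - g$start
      cstart <- g$start + (off %/% 3L) * 3L
      codon <- ref[cstart:(cstart + 2L)]
      codon_alt <- codon; codon_alt[off %% 3L + 1L] <- alt[i]
    } else {
      off <- g$end - p
      cpos <- g$end - (off %/% 3L) * 3L - (0:2)   # genome positions of codon
      codon <- comp_base(ref[cpos])
      codon_alt <- codon; codon_alt[off %% 3L + 1L] <- comp_base(alt[i])
    }
    aa0 <- gc[[chars_to_string(codon)]]
    aa1 <- gc[[chars_to_string(codon_alt)]]
    if (aa0 == aa1) "synonymous" else if (aa1 == "*") "nonsense" else "nonsynonymous"
  }, character(1))
}

truth_indel_effect <- function(pos, len, type, genes, flank = 500L) {
  if (length(pos) == 0) return(character(0))
  vapply(seq_along(pos), function(i) {
    lo <- if (type[i] == "del") pos[i] + 1L else pos[i]
    hi <- if (type[i] == "del") pos[i] + len[i] else pos[i]
    in_cds <- any(genes$start <= hi & genes$end >= lo)
    if (in_cds) {
      if (len[i] %% 3L != 0L) "frameshift" else "inframe_indel"
    } else if (any(genes$start - flank <= hi & genes$end + flank >= lo)) {
      "near_gene_500bp"
    } else "intergenic"
  }, character(1))
}
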