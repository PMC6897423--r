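#' Infer haploid neo-Y SNP alleles from a male/female pair
#'
#' At sites passing depth and genotype-quality filters in both samples, a
#' site homozygous in the female and heterozygous in the male yields the
#' male's non-female allele as the neo-Y genotype. Sites heterozygous in the
#' female are reported with a MISSING (`NA`) allele; a male heterozygote
#' whose alleles do not include the female allele is a genotype
#' inconsistency, also reported MISSING and flagged (expected under
#' sequencing error, not an error condition).
#'
#' @param male,female Data frames of diploid calls for the same strain on
#'   the same coordinate system: columns `pos` (1-based), `a1`, `a2`
#'   (allele characters, `NA` = missing), `dp`, `gq`.
#' @param min_depth Minimum read depth in both samples (default 5).
#' @param min_gq Minimum genotype quality in both samples (default 20).
#' @param strain Optional strain label carried into the output.
#' @return data.table with columns `pos`, `strain`, `allele` (`NA` =
#'   MISSING), `source_class` (`"snp"`), `note`
#'   (`"ok"`/`"female_het"`/`"inconsistent"`). Sites failing filters, with
#'   missing genotypes, or not male-heterozygous are excluded.
#' @export
infer_neoY_snps <- function(male, female, min_depth = 5, min_gq = 20,
                            strain = NA_character_) {
  if (min_depth < 0 || min_gq < 0) stop("negative thresholds")
  m <- data.table::as.data.table(male)[, .(pos, m_a1 = a1, m_a2 = a2,
                                           m_dp = dp, m_gq = gq)]
  f <- data.table::as.data.table(female)[, .(pos, f_a1 = a1, f_a2 = a2,
                                             f_dp = dp, f_gq = gq)]
  if (anyDuplicated(m$pos) || anyDuplicated(f$pos))
    stop("coordinate mismatch: duplicated positions within a table")
  d <- merge(m, f, by = "pos")
  d <- d[m_dp >= min_depth & f_dp >= min_depth & m_gq >= min_gq & f_gq >= min_gq]
  d <- d[!is.na(m_a1) & !is.na(m_a2) & !is.na(f_a1) & !is.na(f_a2)]
  d <- d[m_a1 != m_a2]                       # male heterozygous
  f_het <- d$f_a1 != d$f_a2
  other <- ifelse(d$m_a1 == d$f_a1, d$m_a2,
                  ifelse(d$m_a2 == d$f_a1, d$m_a1, NA_character_))
  allele <- ifelse(f_het, NA_character_, other)
  note <- ifelse(f_het, "female_het",
                 ifelse(is.na(other), "inconsistent", "ok"))
  data.table::data.table(pos = d$pos, strain = strain, allele = allele,
                         source_class = "snp", note = note)[order(pos)]
}

#' Infer Y-linked indels from a male/female pair
#'
#' Indels heterozygous in the male with a homozygous-reference female, plus
#' male-specific homozygous indels (alt/alt male, ref/ref female), are
#' called Y-linked. To avoid mapping artefacts near indels, indels within
#' `merge_window` bp of each other are merged: records are scanned left to
#' right and a record within `merge_window` of the last *retained* record is
#' dropped (greedy chaining — a removed record does not shield later ones).
#' Ties at the same start retain the longest reference span.
#'
#' @param male,female Data frames of indel genotypes: columns `pos`, `ref`,
#'   `alt` (allele strings), `a1`, `a2` (each equal to `ref` or `alt`),
#'   `dp`, `gq`.
#' @param merge_window Merge distance in bp (default 50).
#' @param min_depth,min_gq Filters as in [infer_neoY_snps()].
#' @param strain Optional strain label.
#' @return data.table `pos`, `strain`, `allele` (alt string), `ref`,
#'   `source_class = "indel"`.
#' @export
infer_neoY_indels <- function(male, female, merge_window = 50,
                              min_depth = 5, min_gq = 20,
                              strain = NA_character_) {
  m <- data.table::as.data.table(male)
  f <- data.table::as.data.table(female)[, .(pos, f_a1 = a1, f_a2 = a2,
                                             f_dp = dp, f_gq = gq)]
  d <- merge(m, f, by = "pos")
  d <- d[dp >= min_depth & f_dp >= min_depth & gq >= min_gq & f_gq >= min_gq]
  f_homref <- d$f_a1 == d$ref & d$f_a2 == d$ref
  m_carries <- d$a1 == d$alt | d$a2 == d$alt
  d <- d[f_homref & m_carries]
  d <- d[order(pos, -nchar(ref))]
  keep <- logical(nrow(d))
  last <- -Inf
  for (i in seq_len(nrow(d))) {
    if (d$pos[i] - last > merge_window) {
      keep[i] <- TRUE
      last <- d$pos[i]
    }
  }
  d <- d[keep]
  data.table::data.table(pos = d$pos, strain = strain, allele = d$alt,
                         ref = d$ref, source_class = "indel")
}

#' Classify biallelic sites as shared polymorphisms vs fixed differences
#'
#' Singleton alleles (seen exactly once across the pooled neo-X and neo-Y
#' haplotypes) are removed first; sites left with more than two alleles are
#' dropped. A site where both chromosome classes segregate two alleles is a
#' shared polymorphism; monomorphic for different alleles in each class is a
#' fixed difference; polymorphic in only one class is private to that class;
#' anything else is uninformative.
#'
#' @param neoX_mat,neoY_mat Character matrices (sites x haplotypes) of
#'   haploid alleles, `NA` = missing, with the same row order.
#' @param pos 1-based positions (rows of the matrices).
#' @param window Window size in bp for the per-window summary (default 50 kb,
#'   0-based half-open windows).
#' @return List: `sites` (data.table `pos`, `category`) and `windows`
#'   (per-window counts, informative-site denominator `n_informative`, and
#'   proportions of shared polymorphisms and fixed differences).
#' @export
classify_sites <- function(neoX_mat, neoY_mat, pos, window = 50000) {
  stopifnot(nrow(neoX_mat) == length(pos), nrow(neoY_mat) == length(pos))
  cat_one <- function(x_raw, y_raw) {
    if (length(stats::na.omit(c(x_raw, y_raw))) == 0) stop("empty allele set at a listed site")
    all_tab <- table(c(x_raw, y_raw))
    keep <- names(all_tab)[all_tab >= 2]     # singleton removal
    x <- x_raw[x_raw %in% keep]; y <- y_raw[y_raw %in% keep]
    alleles <- unique(c(x, y))
    if (length(alleles) > 2 || length(alleles) < 2) return("uninformative")
    x_poly <- length(unique(x)) == 2
    y_poly <- length(unique(y)) == 2
    if (x_poly && y_poly) return("shared_polymorphism")
    if (!x_poly && !y_poly) {
      if (length(x) && length(y) && x[1] != y[1]) return("fixed_difference")
      return("uninformative")
    }
    if (x_poly) "private_X" else "private_Y"
  }
  category <- vapply(seq_along(pos), function(i)
    cat_one(stats::na.omit(neoX_mat[i, ]), stats::na.omit(neoY_mat[i, ])),
    character(1))
  sites <- data.table::data.table(pos = pos, category = category)
  w <- window_index(pos, window)
  informative <- category != "uninformative"
  win <- data.table::data.table(win = w, category = category,
                                informative = informative)
  windows <- win[, .(
    n_sites = .N,
    n_informative = sum(informative),
    n_shared = sum(category == "shared_polymorphism"),
    n_fixed = sum(category == "fixed_difference"),
    n_private_X = sum(category == "private_X"),
    n_private_Y = sum(category == "private_Y")), by = win]
  windows[, `:=`(start = win * as.integer(window),
                 end = (win + 1L) * as.integer(window),
                 prop_shared = ifelse(n_informative > 0, n_shared / n_informative, NA_real_),
                 prop_fixed = ifelse(n_informative > 0, n_fixed / n_informative, NA_real_))]
  list(sites = sites, windows = windows[order(win)])
}

#' Group-fixed derived neo-Y variants
#'
#' A variant allele is fixed-derived in a Y group iff it is carried by every
#' non-missing member of the group and absent from all neo-X and all
#' outgroup haplotypes, restricted to a genomic region.
#'
#' @param neoY_calls data.table/data.frame of haploid neo-Y calls: `pos`,
#'   `strain`, `allele` (`NA` = missing).
#' @param groups Named character vector mapping strain -> group.
#' @param neoX_mat Character matrix (sites x haplotypes) of neo-X alleles.
#' @param outgroup_mat Matrix of outgroup (Chr.3) alleles, same rows.
#' @param pos Positions for the matrix rows.
#' @param region Optional bp interval `c(lo, hi)` (1-based, inclusive).
#' @param exclude Strains to drop from their group before assessing fixation
#'   (e.g. a divergent-haplotype strain).
#' @return data.table `group`, `pos`, `allele`.
#' @export
fixed_derived_per_group <- function(neoY_calls, groups, neoX_mat, outgroup_mat,
                                    pos, region = NULL, exclude = NULL) {
  calls <- data.table::as.data.table(neoY_calls)
  if (length(exclude)) calls <- calls[!strain %in% exclude]
  calls[, group := groups[strain]]
  if (!is.null(region)) {
    calls <- calls[pos >= region[1] & pos <= region[2]]
    in_region <- pos >= region[1] & pos <= region[2]
  } else in_region <- rep(TRUE, length(pos))
  out <- list()
  for (g in unique(stats::na.omit(calls$group))) {
    gc <- calls[group == g]
    n_members <- length(unique(gc$strain))
    informative <- gc[!is.na(allele)]
    if (nrow(informative) == 0) {
      warning("group ", g, " has no non-missing calls")
      next
    }
    cand <- informative[, .(n = .N, n_alleles = length(unique(allele)),
                            allele = allele[1]), by = pos]
    # fixed = present in all non-missing members (missing members do not block)
    cand <- cand[n_alleles == 1L & n <= n_members]
    if (nrow(cand) == 0) next
    ridx <- match(cand$pos, pos)
    ok <- !is.na(ridx) & in_region[pmax(ridx, 1L)]
    cand <- cand[ok]; ridx <- ridx[ok]
    absent_x <- !vapply(seq_len(nrow(cand)), function(i)
      cand$allele[i] %in% stats::na.omit(neoX_mat[ridx[i], ]), logical(1))
    absent_o <- !vapply(seq_len(nrow(cand)), function(i)
      cand$allele[i] %in% stats::na.omit(outgroup_mat[ridx[i], ]), logical(1))
    keep <- cand[absent_x & absent_o]
    if (nrow(keep))
      out[[g]] <- data.table::data.table(group = g, pos = keep$pos,
                                         allele = keep$allele)
  }
  if (length(out)) data.table::rbindlist(out)[order(group, pos)]
  else data.table::data.table(group = character(0), pos = integer(0),
                              allele = character(0))
}
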