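#' Classify coding effects of fixed SNP variants
#'
#' Each variant is applied to the reference CDS one at a time (no
#' haplotype-aware codon reconstruction) and translated with the standard
#' genetic code on the transcript strand: an unchanged amino acid is
#' synonymous, a changed one nonsynonymous, a gained stop nonsense.
#' Variants outside any CDS are `near_gene_500bp` when within `flank` bp of
#' a gene span, else `intergenic`. Genes whose CDS length is not a codon
#' multiple are skipped with a message.
#'
#' @param variants Data frame: `pos` (1-based), `alt`, optionally `group`.
#' @param genes Data frame: `gene`, `start`, `end` (1-based inclusive CDS
#'   span), `strand` (`"+"`/`"-"`).
#' @param reference Character vector of reference bases.
#' @param flank Near-gene distance in bp (default 500).
#' @param region Optional bp interval `c(lo, hi)` restriction.
#' @return List: `effects` (data.table pos, alt, group, gene, effect) and
#'   `counts` (per group x effect).
#' @export
classify_snp_effects <- function(variants, genes, reference, flank = 500,
                                 region = NULL) {
  v <- data.table::as.data.table(variants)
  if (!"group" %in% names(v)) v[, group := "all"]
  if (!is.null(region)) v <- v[pos >= region[1] & pos <= region[2]]
  bad <- (genes$end - genes$start + 1L) %% 3L != 0L
  if (any(bad)) {
    message("skipping genes with CDS length not a multiple of 3: ",
            paste(genes$gene[bad], collapse = ", "))
    genes <- genes[!bad, , drop = FALSE]
  }
  gc <- Biostrings::GENETIC_CODE
  eff <- vapply(seq_len(nrow(v)), function(i) {
    p <- v$pos[i]
    hit <- which(genes$start <= p & genes$end >= p)
    if (length(hit) == 0) {
      near <- any(genes$start - flank <= p & genes$end + flank >= p)
      return(if (near) "near_gene_500bp" else "intergenic")
    }
    g <- genes[hit[1], ]
    if (g$strand == "+") {
      off <- p - g$start
      cstart <- g$start + (off %/% 3L) * 3L
      codon <- reference[cstart:(cstart + 2L)]
      mut <- codon; mut[off %% 3L + 1L] <- v$alt[i]
    } else {
      off <- g$end - p
      cpos <- g$end - (off %/% 3L) * 3L - (0:2)
      codon <- comp_base(reference[cpos])
      mut <- codon; mut[off %% 3L + 1L] <- comp_base(v$alt[i])
    }
    aa0 <- gc[[chars_to_string(codon)]]; aa1 <- gc[[chars_to_string(mut)]]
    if (aa0 == aa1) "synonymous" else if (aa1 == "*") "nonsense" else "nonsynonymous"
  }, character(1))
  effects <- data.table::data.table(pos = v$pos, alt = v$alt, group = v$group,
                                    effect = eff)
  counts <- effects[, .N, by = .(group, effect)]
  list(effects = effects, counts = counts)
}

#' Classify fixed indels (frameshift / in-frame / near-gene / intergenic)
#'
#' A CDS indel whose length is not a multiple of 3 is a frameshift;
#' a multiple of 3 is an in-frame indel; outside CDS but within `flank` bp
#' of a gene span it is `near_gene_500bp`, else `intergenic`.
#'
#' @param indels Data frame: `pos` (anchor base, 1-based), `len`, `type`
#'   (`"ins"`/`"del"`), optionally `group`.
#' @param genes Gene table as in [classify_snp_effects()].
#' @param flank Near-gene distance in bp (default 500).
#' @param region Optional bp interval restriction.
#' @return List: `effects` and per-group `counts`.
#' @export
classify_indel_effects <- function(indels, genes, flank = 500, region = NULL) {
  d <- data.table::as.data.table(indels)
  if (!"group" %in% names(d)) d[, group := "all"]
  if (!is.null(region)) d <- d[pos >= region[1] & pos <= region[2]]
  eff <- vapply(seq_len(nrow(d)), function(i) {
    lo <- if (d$type[i] == "del") d$pos[i] + 1L else d$pos[i]
    hi <- if (d$type[i] == "del") d$pos[i] + d$len[i] else d$pos[i]
    if (any(genes$start <= hi & genes$end >= lo)) {
      if (d$len[i] %% 3L != 0L) "frameshift" else "inframe_indel"
    } else if (any(genes$start - flank <= hi & genes$end + flank >= lo)) {
      "near_gene_500bp"
    } else "intergenic"
  }, character(1))
  effects <- data.table::data.table(pos = d$pos, len = d$len, type = d$type,
                                    group = d$group, effect = eff)
  list(effects = effects, counts = effects[, .N, by = .(group, effect)])
}

# NG86 building blocks -------------------------------------------------------

.codon_split <- function(s) {
  n <- nchar(s)
  if (n %% 3 != 0) stop("length mismatch: sequence not a codon multiple")
  substring(s, seq(1, n, 3), seq(3, n, 3))
}

# fraction of the 9 one-step changes of a codon that are synonymous;
# changes to stop codons count as nonsynonymous
.codon_syn_sites <- function(codon, gc) {
  aa <- gc[[codon]]
  bases <- strsplit(codon, "")[[1]]
  syn <- 0
  for (p in 1:3) for (b in setdiff(DNA_BASES, bases[p])) {
    mut <- bases; mut[p] <- b
    if (gc[[paste(mut, collapse = "")]] == aa) syn <- syn + 1
  }
  syn / 3   # = 3 * syn/9
}

# pathway-averaged synonymous/nonsynonymous difference counts between two
# codons; paths through stop codons are excluded unless all paths hit one
.codon_diff_counts <- function(c1, c2, gc) {
  b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
  dpos <- which(b1 != b2)
  if (length(dpos) == 0) return(c(sd = 0, nd = 0))
  paths <- permutations_of(dpos)
  tally <- function(order_pos) {
    cur <- b1; sd <- 0; nd <- 0
    for (p in order_pos) {
      prev_codon <- paste(cur, collapse = "")
      cur[p] <- b2[p]
      new_codon <- paste(cur, collapse = "")
      if (gc[[new_codon]] == "*" && new_codon != c2) return(NULL)  # via stop
      if (gc[[prev_codon]] == gc[[new_codon]]) sd <- sd + 1 else nd <- nd + 1
    }
    c(sd = sd, nd = nd)
  }
  res <- lapply(paths, tally)
  ok <- res[!vapply(res, is.null, logical(1))]
  if (length(ok) == 0) ok <- lapply(paths, function(o) {  # all via stop: keep all
    cur <- b1; sd <- 0; nd <- 0
    for (p in o) {
      prev_codon <- paste(cur, collapse = ""); cur[p] <- b2[p]
      if (gc[[prev_codon]] == gc[[paste(cur, collapse = "")]]) sd <- sd + 1
      else nd <- nd + 1
    }
    c(sd = sd, nd = nd)
  })
  colMeans(do.call(rbind, ok))
}

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    rest <- permutations_of(x[-i])
    out <- c(out, lapply(rest, function(r) c(x[i], r)))
  }
  out
}

#' Ka and Ks between two in-frame CDS sequences (NG86)
#'
#' Nei–Gojobori (1986): expected synonymous/nonsynonymous site counts per
#' codon averaged over both sequences, pathway-averaged difference counting
#' for multi-hit codons, and Jukes–Cantor correction of the proportions.
#' The estimator is symmetric in its arguments. Sequences with an internal
#' stop are flagged and skipped (`NA` result); the ratio is `NA` when
#' `Ks = 0`.
#'
#' @param cds_x,cds_y Equal-length, in-frame CDS strings (identical start
#'   and stop positions).
#' @param gene Optional gene label carried into the result.
#' @return data.frame: gene, ka, ks, ratio, n_codons, flag.
#' @export
compute_kaks <- function(cds_x, cds_y, gene = NA_character_) {
  if (nchar(cds_x) != nchar(cds_y)) stop("length mismatch")
  gc <- Biostrings::GENETIC_CODE
  cx <- .codon_split(toupper(cds_x)); cy <- .codon_split(toupper(cds_y))
  # trim a trailing stop codon if both have one
  n <- length(cx)
  if (n >= 1 && gc[[cx[n]]] == "*" && gc[[cy[n]]] == "*") {
    cx <- cx[-n]; cy <- cy[-n]; n <- n - 1L
  }
  if (any(vapply(cx, function(c) gc[[c]] == "*", logical(1))) ||
      any(vapply(cy, function(c) gc[[c]] == "*", logical(1))))
    return(data.frame(gene = gene, ka = NA_real_, ks = NA_real_,
                      ratio = NA_real_, n_codons = n, flag = "internal_stop"))
  S <- (sum(vapply(cx, .codon_syn_sites, numeric(1), gc = gc)) +
        sum(vapply(cy, .codon_syn_sites, numeric(1), gc = gc))) / 2
  N <- 3 * n - S
  diffs <- vapply(seq_len(n), function(i) .codon_diff_counts(cx[i], cy[i], gc),
                  numeric(2))
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  ks <- jc(pS); ka <- jc(pN)
  data.frame(gene = gene, ka = ka, ks = ks,
             ratio = if (!is.na(ks) && ks > 0 && !is.na(ka)) ka / ks else NA_real_,
             n_codons = n, flag = "ok")
}

#' Per-gene Ka/Ks between neo-X and neo-Y CDS sets
#'
#' Extracts each gene's CDS from two pseudo-reference sequences built on
#' the same annotation (so start/stop positions are identical), removes
#' genes identical between the alleles, and runs [compute_kaks()].
#'
#' @param ref_x,ref_y Character vectors of neo-X and neo-Y chromosome bases.
#' @param genes Gene table (`gene`, `start`, `end`, `strand`).
#' @return data.table of [compute_kaks()] rows (identical genes excluded,
#'   reported in attribute `"n_identical"`).
#' @export
kaks_by_gene <- function(ref_x, ref_y, genes) {
  out <- list(); n_ident <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    sx <- chars_to_string(ref_x[g$start:g$end])
    sy <- chars_to_string(ref_y[g$start:g$end])
    if (g$strand == "-") { sx <- revcomp(sx); sy <- revcomp(sy) }
    if (sx == sy) { n_ident <- n_ident + 1L; next }
    out[[length(out) + 1L]] <- compute_kaks(sx, sy, gene = g$gene)
  }
  res <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(gene = character(0), ka = numeric(0), ks = numeric(0),
                           ratio = numeric(0), n_codons = integer(0),
                           flag = character(0))
  data.table::setattr(res, "n_identical", n_ident)
  res
}
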