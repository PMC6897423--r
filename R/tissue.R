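#' Tissue-specificity index (tau)
#'
#' `tau = sum_i (1 - x_i / x_max) / (N - 1)` over the N tissues: 0 for a
#' perfectly uniform profile, 1 for single-tissue expression. Genes with
#' `tau` above the threshold are deemed tissue-biased and assigned to their
#' two highest-expression tissues. All-zero genes are dropped.
#'
#' @param expr Non-negative matrix, genes x tissues (RPKM-like), with
#'   dimnames.
#' @param threshold Bias threshold on tau (default 0.5).
#' @return data.table: gene, tau, top_tissue1, top_tissue2 (NA unless
#'   tau > threshold).
#' @export
compute_tau <- function(expr, threshold = 0.5) {
  stopifnot(ncol(expr) >= 2)
  if (any(expr < 0)) stop("expression must be >= 0")
  keep <- rowSums(expr) > 0
  if (any(!keep))
    message("dropping ", sum(!keep), " all-zero gene(s): tau undefined")
  expr <- expr[keep, , drop = FALSE]
  xmax <- apply(expr, 1, max)
  tau <- rowSums(1 - expr / xmax) / (ncol(expr) - 1)
  ord <- t(apply(expr, 1, function(r) order(r, decreasing = TRUE)[1:2]))
  tis <- colnames(expr) %||% paste0("tissue", seq_len(ncol(expr)))
  biased <- tau > threshold
  data.table::data.table(
    gene = rownames(expr) %||% as.character(seq_len(nrow(expr))),
    tau = tau,
    top_tissue1 = ifelse(biased, tis[ord[, 1]], NA_character_),
    top_tissue2 = ifelse(biased, tis[ord[, 2]], NA_character_))
}

#' Permutation overlap test for tissue-bias enrichment/depletion
#'
#' Null model: two independent random draws without replacement — the
#' observed number of tissue-biased genes from the Chr.3 gene universe, and
#' the observed number of focal (e.g. neo-X-biased) genes from the filtered
#' universe (assumed nested within the Chr.3 universe) — with the overlap
#' of the two draws recorded per replicate. The draws are realised exactly
#' by a two-stage hypergeometric sample per replicate. Expected count is
#' the median of the null distribution; the p-value is the two-sided
#' percentile `2 * min(P(null >= obs), P(null <= obs))` capped at 1; the
#' display statistic is `sign(obs - expected) * (obs - expected)^2 /
#' max(expected, 1)` (a signed chi-square-style cell statistic).
#'
#' @param n_tissue_biased Number of tissue-biased genes drawn from the
#'   Chr.3 universe.
#' @param n_focal Number of focal genes drawn from the filtered universe.
#' @param universe_chr3 Size of the Chr.3 gene universe.
#' @param universe_filtered Size of the filtered universe (must not exceed
#'   `universe_chr3`; genes passing the expression filter).
#' @param observed Observed overlap count.
#' @param reps Permutation replicates (default 100000; a warning is issued
#'   below 1000).
#' @param seed Integer seed.
#' @return List: observed, expected (median of null), p, signed_stat,
#'   null_mean, reps.
#' @export
permutation_overlap_test <- function(n_tissue_biased, n_focal,
                                     universe_chr3, universe_filtered,
                                     observed, reps = 100000, seed = 1L) {
  if (universe_filtered > universe_chr3)
    stop("filtered universe must be nested within the Chr.3 universe")
  if (n_tissue_biased > universe_chr3 || n_focal > universe_filtered)
    stop("draw sizes exceed their universe sizes")
  if (observed > min(n_tissue_biased, n_focal))
    stop("observed overlap exceeds the smaller draw")
  if (reps < 1000) warning("reps < 1000: unstable percentile")
  set.seed(seed)
  # stage 1: tissue-biased draws landing inside the filtered universe
  x <- stats::rhyper(reps, universe_filtered,
                     universe_chr3 - universe_filtered, n_tissue_biased)
  # stage 2: focal draws hitting those genes
  null <- stats::rhyper(reps, x, universe_filtered - x, n_focal)
  expected <- stats::median(null)
  p <- min(1, 2 * min(mean(null >= observed), mean(null <= observed)))
  delta <- observed - expected
  list(observed = observed, expected = expected, p = p,
       signed_stat = sign(delta) * delta^2 / max(expected, 1),
       null_mean = mean(null), reps = reps)
}
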