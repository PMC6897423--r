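# Windowed population-genetic statistics over haploid allele matrices.
#
# All functions take a sites-by-haplotypes character matrix (NA = missing
# call), 1-based positions, and the chromosome length. Windows are 0-based
# half-open [start, end) tiles; the window denominator is the full window
# span in bp (monomorphic and uncalled bases contribute zero), matching the
# convention of vcftools --window-pi. Missing calls are dropped per site
# (pairwise complete), with the number of contributing sites recorded.

# per-site allele count matrix over A/C/G/T
.allele_counts <- function(mat) {
  out <- vapply(DNA_BASES, function(b) rowSums(mat == b, na.rm = TRUE),
                numeric(nrow(mat)))
  matrix(out, nrow = nrow(mat), ncol = length(DNA_BASES),
         dimnames = list(NULL, DNA_BASES))
}

.site_pi <- function(mat) {
  cnt <- .allele_counts(mat)
  k <- rowSums(cnt)
  num <- rowSums(cnt * (k - cnt)) / 2
  den <- k * (k - 1) / 2
  ifelse(k >= 2, num / den, NA_real_)
}

.win_table <- function(pos, L, window) {
  w <- window_index(pos, window)
  tiles <- tile_windows(L, window)
  tiles$win <- window_index(tiles$start + 1L, window)
  list(w = w, tiles = tiles)
}

#' Windowed nucleotide diversity (pi)
#'
#' Per-site pi is the unbiased pairwise-difference estimator
#' `sum_a c_a (k - c_a) / 2 / choose(k, 2)` over the `k` non-missing
#' haplotypes; the window value sums per-site pi over the full window span
#' in bp.
#'
#' @param mat Character matrix, sites x haplotypes (`NA` = missing).
#' @param pos 1-based site positions.
#' @param L Chromosome length in bp.
#' @param window Window size in bp (default 50 kb).
#' @param pop Population label for the output.
#' @param chrom Chromosome name.
#' @return data.table: chrom, start, end, stat, pop1, pop2, value, n_sites.
#' @export
windowed_pi <- function(mat, pos, L, window = 50000, pop = "pop",
                        chrom = "chrom") {
  stopifnot(ncol(mat) >= 2, window > 0)
  ps <- .site_pi(mat)
  wt <- .win_table(pos, L, window)
  agg <- data.table::data.table(win = wt$w, pi = ps)[
    , .(s = sum(pi, na.rm = TRUE), n_sites = sum(!is.na(pi))), by = win]
  out <- merge(data.table::as.data.table(wt$tiles), agg, by = "win", all.x = TRUE)
  out[is.na(s), s := 0][is.na(n_sites), n_sites := 0L]
  data.table::data.table(chrom = chrom, start = out$start, end = out$end,
                         stat = "pi", pop1 = pop, pop2 = NA_character_,
                         value = out$s / (out$end - out$start),
                         n_sites = out$n_sites)[order(start)]
}

# Weir & Cockerham (1984) variance components for haploid samples at one
# biallelic site: MSP/MSG formulation with the heterozygosity terms absent.
.wc_components <- function(cntA, cntB) {
  nA <- rowSums(cntA); nB <- rowSums(cntB)
  tot <- cntA + cntB
  # choose the first segregating allele as "the" allele
  amax <- max.col(tot, ties.method = "first")
  idx <- cbind(seq_len(nrow(tot)), amax)
  pA <- cntA[idx] / nA; pB <- cntB[idx] / nB
  n <- nA + nB
  pbar <- (cntA[idx] + cntB[idx]) / n
  r <- 2
  nc <- (n - (nA^2 + nB^2) / n) / (r - 1)
  msp <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / (r - 1)
  msg <- (nA * pA * (1 - pA) + nB * pB * (1 - pB)) / ((nA - 1) + (nB - 1))
  a <- (msp - msg) / nc                      # among-population component
  b <- msg                                   # within-population component
  list(num = a, den = a + b)
}

#' Windowed F_ST between two populations
#'
#' Default estimator is the Weir–Cockerham (1984) weighted ratio of sums
#' (variance components summed over sites within each window before the
#' ratio), reduced to its haploid form. `estimator = "hudson"` gives the
#' `1 - H_within / H_between` cross-check (ratio of window averages).
#' Only biallelic sites with both populations called are used.
#'
#' @inheritParams windowed_pi
#' @param matA,matB Haplotype matrices for the two populations (same rows).
#' @param estimator `"weir_cockerham"` (default) or `"hudson"`.
#' @param popA,popB Population labels.
#' @return data.table as in [windowed_pi()] with `stat = "fst"`.
#' @export
windowed_fst <- function(matA, matB, pos, L, window = 50000,
                         estimator = c("weir_cockerham", "hudson"),
                         popA = "popA", popB = "popB", chrom = "chrom") {
  estimator <- match.arg(estimator)
  if (ncol(matA) < 1 || ncol(matB) < 1) stop("empty population")
  cntA <- .allele_counts(matA); cntB <- .allele_counts(matB)
  tot <- cntA + cntB
  nallele <- rowSums(tot > 0)
  kA <- rowSums(cntA); kB <- rowSums(cntB)
  usable <- nallele == 2 & kA >= 1 & kB >= 1
  wt <- .win_table(pos, L, window)
  if (estimator == "weir_cockerham") {
    comp <- .wc_components(cntA, cntB)
    dt <- data.table::data.table(win = wt$w, num = comp$num, den = comp$den,
                                 use = usable & kA >= 2 & kB >= 2)
    agg <- dt[use == TRUE, .(value = sum(num) / sum(den), n_sites = .N), by = win]
  } else {
    hw <- (.site_pi(matA) + .site_pi(matB)) / 2
    hb <- .site_dxy(cntA, cntB, kA, kB)
    dt <- data.table::data.table(win = wt$w, hw = hw, hb = hb, use = usable)
    agg <- dt[use == TRUE & !is.na(hw) & !is.na(hb),
              .(value = 1 - mean(hw) / mean(hb), n_sites = .N), by = win]
  }
  out <- merge(data.table::as.data.table(wt$tiles), agg, by = "win", all.x = TRUE)
  out[is.na(n_sites), n_sites := 0L]
  data.table::data.table(chrom = chrom, start = out$start, end = out$end,
                         stat = "fst", pop1 = popA, pop2 = popB,
                         value = out$value, n_sites = out$n_sites)[order(start)]
}

.site_dxy <- function(cntA, cntB, kA, kB) {
  same <- rowSums((cntA / kA) * (cntB / kB))
  ifelse(kA >= 1 & kB >= 1, 1 - same, NA_real_)
}

#' Windowed absolute (D_XY) and net (D_A) divergence
#'
#' Per-site D_XY is the mean per-bp difference over all inter-population
#' haplotype pairs, summed over sites and divided by the window span.
#' `Da = Dxy - (pi_A + pi_B) / 2`, computed per window. Negative Da values
#' are reported, not clipped. When the two matrices are the identical
#' haplotype set, self-pairs are excluded, so that `Dxy` reduces exactly to
#' `pi` (and `Da` to zero).
#'
#' @inheritParams windowed_fst
#' @return data.table with `stat` in `{"dxy", "da"}`.
#' @export
windowed_divergence <- function(matA, matB, pos, L, window = 50000,
                                popA = "popA", popB = "popB",
                                chrom = "chrom") {
  if (ncol(matA) < 1 || ncol(matB) < 1) stop("empty population")
  cntA <- .allele_counts(matA); cntB <- .allele_counts(matB)
  kA <- rowSums(cntA); kB <- rowSums(cntB)
  dxy_s <- if (identical(matA, matB)) .site_pi(matA)   # self-pairs excluded
           else .site_dxy(cntA, cntB, kA, kB)
  piA_s <- .site_pi(matA); piB_s <- .site_pi(matB)
  wt <- .win_table(pos, L, window)
  dt <- data.table::data.table(win = wt$w, dxy = dxy_s, piA = piA_s, piB = piB_s)
  agg <- dt[, .(dxy = sum(dxy, na.rm = TRUE),
                piA = sum(piA, na.rm = TRUE),
                piB = sum(piB, na.rm = TRUE),
                n_sites = sum(!is.na(dxy))), by = win]
  out <- merge(data.table::as.data.table(wt$tiles), agg, by = "win", all.x = TRUE)
  for (cc in c("dxy", "piA", "piB")) out[is.na(get(cc)), (cc) := 0]
  out[is.na(n_sites), n_sites := 0L]
  span <- out$end - out$start
  dxy <- out$dxy / span
  da <- dxy - (out$piA / span + out$piB / span) / 2
  data.table::rbindlist(list(
    data.table::data.table(chrom = chrom, start = out$start, end = out$end,
                           stat = "dxy", pop1 = popA, pop2 = popB,
                           value = dxy, n_sites = out$n_sites),
    data.table::data.table(chrom = chrom, start = out$start, end = out$end,
                           stat = "da", pop1 = popA, pop2 = popB,
                           value = da, n_sites = out$n_sites)))[order(stat, start)]
}
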