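#' Build per-sample pseudo-references with IUPAC ambiguities
#'
#' Substitutes each sample's SNP alleles into the reference: homozygous alt
#' becomes the alt base, heterozygous becomes the two-allele IUPAC code, and
#' missing genotypes retain the reference base. Indels are ignored
#' (substitution-only). Sequences are stored sparsely (reference plus
#' per-sample variant lists) and materialised on demand.
#'
#' @param reference Character vector of reference bases (or a single string).
#' @param genotypes Data frame of diploid calls: `pos` (1-based), `sample`,
#'   `a1`, `a2` (single-base alleles; `NA` = missing). For haploid inputs
#'   (e.g. inferred neo-Y calls) see `haploid` below.
#' @param haploid Optional data frame `pos`, `sample`, `allele` of haploid
#'   calls; `NA` alleles are masked to `"N"` (removed sites must not pass as
#'   reference), per the treatment of MISSING neo-Y calls.
#' @return `pseudo_refs` object: list(`ref`, `variants` = named list of
#'   data.frames `pos`, `base`).
#' @export
build_pseudoreferences <- function(reference, genotypes = NULL, haploid = NULL) {
  ref <- if (length(reference) == 1L && nchar(reference[1]) > 1L)
    strsplit(reference, "")[[1]] else reference
  variants <- list()
  if (!is.null(genotypes)) {
    g <- data.table::as.data.table(genotypes)
    if (any(g$pos < 1 | g$pos > length(ref))) stop("genotype position outside reference")
    for (s in unique(g$sample)) {
      gs <- g[sample == s & !is.na(a1) & !is.na(a2)]
      base <- ifelse(gs$a1 == gs$a2, gs$a1, iupac_code(gs$a1, gs$a2))
      keep <- base != ref[gs$pos]
      variants[[s]] <- data.frame(pos = gs$pos[keep], base = base[keep])
    }
  }
  if (!is.null(haploid)) {
    h <- data.table::as.data.table(haploid)
    if (any(h$pos < 1 | h$pos > length(ref))) stop("call position outside reference")
    for (s in unique(h$sample)) {
      hs <- h[sample == s]
      base <- ifelse(is.na(hs$allele), "N", hs$allele)
      keep <- base != ref[hs$pos]
      variants[[s]] <- data.frame(pos = hs$pos[keep], base = base[keep])
    }
  }
  structure(list(ref = ref, variants = variants), class = "pseudo_refs")
}

#' Materialise a pseudo-reference sequence
#' @param prefs A `pseudo_refs` object.
#' @param sample Sample name.
#' @param from,to Optional 1-based inclusive slice.
#' @return Single character string.
#' @export
pseudoref_sequence <- function(prefs, sample, from = 1L, to = length(prefs$ref)) {
  v <- prefs$variants[[sample]]
  if (is.null(v)) stop("unknown sample: ", sample)
  s <- apply_variants(prefs$ref, v$pos, v$base)
  chars_to_string(s[from:to])
}

#' Slice pseudo-references into per-window alignments
#'
#' Sequences are positionally homologous by construction, so a window
#' alignment is a coordinate slice: it stores the window span and the
#' alleles at positions where any sample differs from the reference;
#' all other positions are implied invariant. Windows are 0-based
#' half-open; the final window is truncated at the chromosome end.
#'
#' @param prefs A `pseudo_refs` object.
#' @param window Window size in bp (default 200 kb).
#' @param step Step in bp (default = `window`, non-overlapping).
#' @param samples Samples to include (default all).
#' @return List of `window_alignment` objects: list(`start`, `end` (0-based
#'   half-open), `pos` (1-based variant positions), `mat` (sites x samples
#'   character matrix), `ref_bases`, `L` = window span,
#'   `zero_variation` flag).
#' @export
window_alignments <- function(prefs, window = 200000, step = window,
                              samples = names(prefs$variants)) {
  L <- length(prefs$ref)
  tiles <- tile_windows(L, window, step)
  vlist <- prefs$variants[samples]
  lapply(seq_len(nrow(tiles)), function(i) {
    lo <- tiles$start[i]; hi <- tiles$end[i]           # 0-based half-open
    pos <- sort(unique(unlist(lapply(vlist, function(v)
      if (is.null(v)) integer(0) else v$pos[v$pos > lo & v$pos <= hi]))))
    mat <- matrix(prefs$ref[pos], nrow = length(pos), ncol = length(samples),
                  dimnames = list(NULL, samples))
    for (s in samples) {
      v <- vlist[[s]]
      if (is.null(v)) next
      vv <- v[v$pos %in% pos, , drop = FALSE]
      if (nrow(vv)) mat[match(vv$pos, pos), s] <- vv$base
    }
    zero_var <- !any(apply(mat, 1, function(r) {
      r <- r[r != "N" & !is.na(r)]
      length(unique(r)) >= 2
    }))
    structure(list(start = lo, end = hi, pos = pos, mat = mat,
                   ref_bases = prefs$ref[pos], L = hi - lo,
                   zero_variation = isTRUE(zero_var)),
              class = "window_alignment")
  })
}

#' Materialise a window alignment as full-length sequences
#' @param aln A `window_alignment`.
#' @param ref Reference character vector (bases) for the whole chromosome.
#' @return Named character vector of sequences, one per sample.
#' @export
alignment_sequences <- function(aln, ref) {
  span <- (aln$start + 1L):aln$end
  vapply(colnames(aln$mat), function(s) {
    seq <- ref[span]
    if (length(aln$pos)) seq[aln$pos - aln$start] <- aln$mat[, s]
    chars_to_string(seq)
  }, character(1))
}

#' Pairwise distances from a window alignment
#'
#' Per-site match scores treat IUPAC ambiguity codes as partial matches:
#' `match(s1, s2) = |sets intersect| / max(|set1|, |set2|)`, so a base
#' versus a two-base code sharing it scores 1/2. `N` and missing calls are
#' excluded pairwise (the denominator shrinks accordingly). Invariant
#' positions outside `aln$pos` count as full matches. The raw mismatch
#' proportion is Jukes–Cantor corrected; pairs at or beyond saturation
#' (p >= 0.75) fall back to the uncorrected p-distance with a warning.
#'
#' @param aln A `window_alignment`.
#' @param correction `"JC"` (default) or `"none"`.
#' @return A `dist` object over the samples.
#' @export
alignment_distances <- function(aln, correction = c("JC", "none")) {
  correction <- match.arg(correction)
  samples <- colnames(aln$mat)
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  if (length(aln$pos)) {
    sets <- IUPAC_SETS
    size <- lengths(sets)
    code_idx <- function(x) match(x, names(sets))
    idx <- apply(aln$mat, 2, code_idx)
    idx <- matrix(idx, ncol = n)
    valid <- !is.na(idx) & names(sets)[ifelse(is.na(idx), 1L, idx)] != "N"
    # pairwise mismatch via set overlap
    overlap <- outer(seq_along(sets), seq_along(sets),
                     Vectorize(function(i, j)
                       length(intersect(sets[[i]], sets[[j]])) /
                         max(size[i], size[j])))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ok <- valid[, i] & valid[, j]
      mism <- sum(1 - overlap[cbind(idx[ok, i], idx[ok, j])])
      denom <- aln$L - sum(!ok)
      p <- if (denom > 0) mism / denom else NA_real_
      d[i, j] <- d[j, i] <- p
    }
  }
  if (correction == "JC") {
    sat <- d >= 0.75
    if (any(sat & upper.tri(d))) {
      warning("saturated distances (p >= 0.75); using uncorrected p-distance")
    } else {
      d <- -0.75 * log(1 - 4 * d / 3)
    }
  }
  stats::as.dist(d)
}
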