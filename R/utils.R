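# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC ambiguity codes as base sets (subset actually needed: 1- and 2-base
# codes for diploid SNP genotypes, plus 3/4-base codes so arbitrary input
# sequences classify cleanly).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# two alleles -> IUPAC code (hets) or the base itself (homs)
iupac_code <- function(a1, a2) {
  codes <- vapply(IUPAC_SETS[c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M")],
                  paste, character(1), collapse = "")
  key <- ifelse(a1 <= a2, paste0(a1, a2), paste0(a2, a1))
  key <- sub("^(.)\\1$", "\\1", key)
  out <- names(codes)[match(key, codes)]
  if (anyNA(out)) stop("non-ACGT alleles cannot be IUPAC-encoded: ",
                       paste(unique(key[is.na(out)]), collapse = ", "))
  out
}

# 0-based half-open window tiling of [0, L); final window truncated at L
tile_windows <- function(L, window, step = window) {
  stopifnot(window > 0, step > 0, L > 0)
  starts <- seq(0L, max(0L, as.integer(ceiling((L - 1) / step)) * step), by = step)
  starts <- starts[starts < L]
  data.frame(start = starts, end = pmin(starts + window, L))
}

window_index <- function(pos, window) as.integer((pos - 1L) %/% window)

revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTRYKMBDHVacgt", "TGCAYRMKVHDBtgca",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

# substitute sparse variants into a reference character vector
apply_variants <- function(ref_chars, pos, base) {
  out <- ref_chars
  if (length(pos)) out[pos] <- base
  out
}

chars_to_string <- function(x) paste(x, collapse = "")

# deterministic child seed streams derived from one user seed (kept < 2^31)
derive_seed <- function(seed, k) as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
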