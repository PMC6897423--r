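# Shared fixtures, built in code and memoised for the test run.

# small scaled-down group scheme for short chromosomes
small_groups <- function(L) {
  list(
    list(name = "Y1", n_strains = 3, recomb_stop_kya = 106.8,
         breakpoints = c(0.2, 0.8) * L),
    list(name = "Y2", n_strains = 2, recomb_stop_kya = 89.6,
         breakpoints = c(0.2, 0.6) * L),
    list(name = "Y3", n_strains = 3, recomb_stop_kya = 135.2,
         breakpoints = c(0.2, 0.9) * L)
  )
}

small_config <- function(L = 5e5, seed = 1, ...) {
  args <- list(chromosome_length = L, n_genes = 10,
               y_groups = small_groups(L), nasuta_block = c(0, 0.1 * L),
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots    # flat override (modifyList merges nested lists)
  do.call(sim_config, args)
}

# cohort -> window trees + topologies (the tree-building pipeline)
cohort_trees <- function(co, window = 2e5) {
  haps <- co$haplotypes
  prefs <- build_pseudoreferences(co$reference,
    haploid = data.frame(pos = rep(haps$pos, ncol(haps$mat)),
                         sample = rep(colnames(haps$mat), each = length(haps$pos)),
                         allele = as.vector(haps$mat)))
  alns <- window_alignments(prefs, window = window)
  out_tips <- names(haps$classes)[haps$classes == "chr3"]
  trees <- lapply(alns, infer_tree, outgroup = out_tips)
  list(trees = trees,
       topologies = lapply(trees, classify_topology, groups = haps$classes),
       groups = haps$classes)
}

# the default 2-Mb cohort plus its trees, built once per test run
default_cohort_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- simulate_cohort(sim_config(seed = 1))
      cache <<- c(list(cohort = co), cohort_trees(co))
    }
    cache
  }
})

# haploid neo-Y calls for every strain of a cohort via the male/female rule
all_neoY_calls <- function(co, ...) {
  g <- co$genotypes
  strains <- unique(co$samples$strain[co$samples$sex == "male"])
  data.table::rbindlist(lapply(strains, function(s)
    infer_neoY_snps(g[g$sample == paste0("male_", s), ],
                    g[g$sample == paste0("female_", s), ], strain = s, ...)))
}

strain_groups <- function(co) {
  strains <- unique(co$samples$strain[co$samples$sex == "male"])
  stats::setNames(sub("_[0-9]+$", "", strains), strains)
}

class_matrix <- function(co, class) {
  keep <- names(co$haplotypes$classes)[co$haplotypes$classes == class]
  co$haplotypes$mat[, keep, drop = FALSE]
}

# brute-force popgen oracles (all-pairs loops, independent of the package's
# vectorised counting); per site, averaged over pairs with both members
# called — the pairwise-complete convention
brute_pi <- function(mat, L) {
  n <- ncol(mat); tot <- 0
  for (s in seq_len(nrow(mat))) {
    diffs <- 0; pairs <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (!is.na(mat[s, i]) && !is.na(mat[s, j])) {
        pairs <- pairs + 1
        diffs <- diffs + (mat[s, i] != mat[s, j])
      }
    }
    if (pairs > 0) tot <- tot + diffs / pairs
  }
  tot / L
}

brute_dxy <- function(matA, matB, L) {
  tot <- 0
  for (s in seq_len(nrow(matA))) {
    diffs <- 0; pairs <- 0
    for (i in seq_len(ncol(matA))) for (j in seq_len(ncol(matB))) {
      if (!is.na(matA[s, i]) && !is.na(matB[s, j])) {
        pairs <- pairs + 1
        diffs <- diffs + (matA[s, i] != matB[s, j])
      }
    }
    if (pairs > 0) tot <- tot + diffs / pairs
  }
  tot / L
}

# least-squares topology fit for a 4-taxon distance matrix: returns the pair
# grouped with taxon 1 under the best-fitting resolved topology
ls_best_quartet <- function(d) {
  taxa <- rownames(d)
  splits <- list(c(2, 3, 4), c(3, 2, 4), c(4, 2, 3))
  rss <- vapply(splits, function(s) {
    # topology ((1,s1),(s2,s3)): 5 edges; least squares on the 6 distances
    a <- taxa[1]; b <- taxa[s[1]]; c1 <- taxa[s[2]]; c2 <- taxa[s[3]]
    X <- rbind(
      c(1, 1, 0, 0, 0),  # d(a,b)
      c(1, 0, 1, 0, 1),  # d(a,c1)
      c(1, 0, 0, 1, 1),  # d(a,c2)
      c(0, 1, 1, 0, 1),  # d(b,c1)
      c(0, 1, 0, 1, 1),  # d(b,c2)
      c(0, 0, 1, 1, 0))  # d(c1,c2)
    y <- c(d[a, b], d[a, c1], d[a, c2], d[b, c1], d[b, c2], d[c1, c2])
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }, numeric(1))
  taxa[splits[[which.min(rss)]][1]]
}

# set-inclusion oracle for maximal exclusively-neo-Y clades: enumerate all
# clades via ape::prop.part, keep Y-only ones (plus Y-tip singletons), count
# those not contained in a larger Y-only one
oracle_count_clades <- function(phy, y_tips) {
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  clades <- lapply(pp, function(i) labs[i])
  clades <- c(clades, as.list(phy$tip.label))
  yonly <- Filter(function(s) all(s %in% y_tips), clades)
  yonly <- unique(lapply(yonly, sort))
  if (length(yonly) == 0) return(0L)
  maximal <- vapply(seq_along(yonly), function(i)
    !any(vapply(seq_along(yonly), function(j)
      i != j && all(yonly[[i]] %in% yonly[[j]]), logical(1))), logical(1))
  sum(maximal)
}

chars_to_string_test <- function(x) paste(x, collapse = "")

apply_variants_for_test <- function(ref, pos, alt) {
  if (length(pos)) ref[pos] <- alt
  ref
}

# wrap an ape tree as a window_tree
as_window_tree <- function(phy, start = 0, end = 2e5, zero_variation = FALSE) {
  if (is.character(phy)) phy <- ape::read.tree(text = phy)
  structure(list(tree = phy, start = start, end = end,
                 zero_variation = zero_variation), class = "window_tree")
}

# independent NG86 oracle: exhaustive site counting and pathway enumeration,
# written against the definitions rather than the package's code
oracle_ng86 <- function(s1, s2) {
  gc <- Biostrings::GENETIC_CODE
  codons <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  syn_sites <- function(cd) {
    b <- strsplit(cd, "")[[1]]; syn <- 0
    for (p in 1:3) for (nb in setdiff(c("A", "C", "G", "T"), b[p])) {
      m <- b; m[p] <- nb
      if (gc[[paste(m, collapse = "")]] == gc[[cd]]) syn <- syn + 1
    }
    syn / 3
  }
  path_counts <- function(c1, c2) {
    b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
    dp <- which(b1 != b2)
    if (!length(dp)) return(c(0, 0))
    perms <- if (length(dp) == 1) list(dp) else
      if (length(dp) == 2) list(dp, rev(dp)) else
        lapply(seq_len(6), function(k) {
          o <- rbind(c(1,2,3),c(1,3,2),c(2,1,3),c(2,3,1),c(3,1,2),c(3,2,1))[k,]
          dp[o]
        })
    res <- list()
    for (pm in perms) {
      cur <- b1; sd <- 0; nd <- 0; ok <- TRUE
      for (p in pm) {
        old <- paste(cur, collapse = ""); cur[p] <- b2[p]
        new <- paste(cur, collapse = "")
        if (gc[[new]] == "*" && new != c2) { ok <- FALSE; break }
        if (gc[[old]] == gc[[new]]) sd <- sd + 1 else nd <- nd + 1
      }
      if (ok) res[[length(res) + 1]] <- c(sd, nd)
    }
    colMeans(do.call(rbind, res))
  }
  c1 <- codons(s1); c2 <- codons(s2)
  S <- (sum(vapply(c1, syn_sites, 1)) + sum(vapply(c2, syn_sites, 1))) / 2
  N <- 3 * length(c1) - S
  dd <- rowSums(vapply(seq_along(c1), function(i) path_counts(c1[i], c2[i]),
                       numeric(2)))
  pS <- dd[1] / S; pN <- dd[2] / N
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA
  c(ka = jc(pN), ks = jc(pS))
}

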