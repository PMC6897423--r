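#' Smooth solitary windows in a label sequence
#'
#' A run of length 1 whose two flanking windows carry the same label is
#' reassigned that label; runs of length >= 2 and chromosome-end solos (one
#' flank only) are unchanged. `NA` labels (excluded windows) never match and
#' are never reassigned. The pass is repeated to a fixpoint (alternating
#' label patterns would otherwise oscillate), making the operation
#' idempotent; runs of length >= 2 in the input are never modified.
#'
#' @param labels Vector of window labels.
#' @return Smoothed vector.
#' @export
smooth_solo <- function(labels) {
  n <- length(labels)
  if (n < 3) return(labels)
  cur <- labels
  for (iter in seq_len(n)) {
    r <- rle(as.character(cur))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    out <- cur
    for (k in seq_along(r$lengths)) {
      if (r$lengths[k] != 1L || k == 1L || k == length(r$lengths)) next
      left <- r$values[k - 1]; right <- r$values[k + 1]
      if (is.na(left) || is.na(right) || is.na(r$values[k])) next
      if (left == right && left != r$values[k]) out[starts[k]] <- cur[ends[k - 1]]
    }
    if (identical(out, cur)) break
    cur <- out
  }
  cur
}

#' Paint neo-Y haplotype labels along windows
#'
#' Per window, each maximal exclusively-neo-Y clade receives a label; neo-Ys
#' in the same clade share the label. Labels are matched across adjacent
#' windows by maximal overlap of member sets (ties resolved toward the
#' left window's smaller label), solitary mismatching windows are smoothed
#' per [smooth_solo()], and label transitions yield breakpoints.
#'
#' @param trees List of `window_tree` objects in genomic order.
#' @param groups Named character vector tip -> class (as in
#'   [classify_topology()]).
#' @return `haplotype_painting`: list(`labels` = windows x neo-Y-samples
#'   integer matrix (NA for excluded windows), `windows` = data.frame of
#'   window spans, `breakpoints` = data.table(sample, pos) with positions at
#'   the boundary between differing windows).
#' @export
paint_haplotypes <- function(trees, groups) {
  y_samples <- names(groups)[!groups %in% c("neoX", "chr3")]
  if (length(y_samples) == 0) stop("window with zero neo-Y tips: no neo-Y samples")
  nw <- length(trees)
  lab <- matrix(NA_integer_, nrow = nw, ncol = length(y_samples),
                dimnames = list(NULL, y_samples))
  next_label <- 1L
  prev_members <- list()   # label -> member vector, from previous painted window
  for (w in seq_len(nw)) {
    tr <- trees[[w]]
    if (isTRUE(tr$zero_variation)) next
    cnt <- count_neoY_clades(tr$tree, y_samples)
    members <- attr(cnt, "members")
    if (length(members) == 0) next
    ord <- order(vapply(members, `[`, character(1), 1))
    members <- members[ord]
    assigned <- rep(NA_integer_, length(members))
    if (length(prev_members)) {
      ov <- sapply(members, function(m)
        vapply(prev_members, function(p) length(intersect(m, p)), numeric(1)))
      ov <- matrix(ov, nrow = length(prev_members))
      repeat {
        if (max(ov) <= 0) break
        best <- which(ov == max(ov), arr.ind = TRUE)
        best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
        assigned[best[2]] <- as.integer(names(prev_members)[best[1]])
        ov[best[1], ] <- -1; ov[, best[2]] <- -1
      }
    }
    for (i in seq_along(members)) {
      if (is.na(assigned[i])) { assigned[i] <- next_label; next_label <- next_label + 1L }
      lab[w, members[[i]]] <- assigned[i]
    }
    prev_members <- stats::setNames(members, assigned)
  }
  for (s in y_samples) lab[, s] <- smooth_solo(lab[, s])
  wins <- data.frame(
    start = vapply(trees, function(t) t$start %||% NA_real_, numeric(1)),
    end = vapply(trees, function(t) t$end %||% NA_real_, numeric(1)))
  bps <- list()
  for (s in y_samples) {
    v <- lab[, s]
    obs <- which(!is.na(v))
    if (length(obs) >= 2) {
      ch <- obs[-1][v[obs[-1]] != v[obs[-length(obs)]]]
      if (length(ch))
        bps[[s]] <- data.table::data.table(sample = s, pos = wins$start[ch])
    }
  }
  structure(list(labels = lab, windows = wins,
                 breakpoints = if (length(bps)) data.table::rbindlist(bps)
                               else data.table::data.table(sample = character(0),
                                                           pos = numeric(0))),
            class = "haplotype_painting")
}

#' Convert a median normalized h-to-tip fraction into a haplotype age
#' @param fraction Normalized h-to-tip fraction(s) in `[0, 1]`.
#' @param species_split_kya Species split time in kyr (default 250).
#' @return Age(s) in kyr (`fraction * species_split_kya`).
#' @export
age_from_fraction <- function(fraction, species_split_kya = 250) {
  stopifnot(all(fraction >= 0 & fraction <= 1, na.rm = TRUE))
  fraction * species_split_kya
}

#' Date neo-Y haplotype groups from branch-length ratios
#'
#' For each Y group and each eligible window (species sorted, group
#' monophyletic, variable sites present, optionally inside a restriction
#' interval): the s node is the most recent common ancestor of all ingroup
#' and outgroup tips; the h node is the parent of the group's clade;
#' `s_to_h` is the path length between them; `h_to_tip` is averaged over
#' the neo-X tips of the clade's sister subtree (and, separately, over the
#' group's own neo-Y tips). The per-window normalized fraction
#' `h_to_tip / (s_to_h + h_to_tip)` uses the neo-X h-to-tip; the group's
#' fraction is the median over windows and the age is the fraction times
#' the species split time. 95% CIs are nonparametric bootstrap over windows.
#'
#' @param trees List of `window_tree` objects.
#' @param topologies List of `topology_class` objects (same order), e.g.
#'   from [classify_topology()]; computed on the fly if `NULL`.
#' @param groups Named character vector tip -> class.
#' @param species_split_kya Species split time in kyr (default 250).
#' @param restrict Optional bp interval `c(lo, hi)`: only windows fully
#'   inside it are used.
#' @param boot Bootstrap replicates for the CI (default 1000).
#' @param seed Seed for the bootstrap.
#' @return List: `records` (per window per group branch lengths and
#'   fractions) and `estimates` (per group: medians, normalized fraction,
#'   age in kyr, 95% CI, n_windows).
#' @export
date_haplotypes <- function(trees, topologies = NULL, groups,
                            species_split_kya = 250, restrict = NULL,
                            boot = 1000, seed = 1L) {
  if (is.null(topologies)) topologies <- lapply(trees, classify_topology, groups = groups)
  y_groups <- setdiff(unique(groups), c("neoX", "chr3"))
  recs <- list()
  for (w in seq_along(trees)) {
    tr <- trees[[w]]; tc <- topologies[[w]]
    if (isTRUE(tr$zero_variation) || !isTRUE(tc$species_sorted)) next
    if (!is.null(restrict) &&
        !(isTRUE(tr$start >= restrict[1]) && isTRUE(tr$end <= restrict[2]))) next
    phy <- tr$tree
    tips <- phy$tip.label
    cls <- groups[tips]
    dn <- ape::dist.nodes(phy)
    nt <- ape::Ntip(phy)
    parent <- integer(nt + phy$Nnode)
    parent[phy$edge[, 2]] <- phy$edge[, 1]
    s_node <- ape::getMRCA(phy, tips)
    sets <- .node_tipsets(phy)
    for (g in y_groups) {
      if (!isTRUE(tc$group_monophyletic[[g]])) next
      g_tips <- tips[cls == g]
      if (length(g_tips) == 0) next
      g_idx <- match(g_tips, tips)
      node <- if (length(g_idx) == 1) g_idx else ape::getMRCA(phy, g_tips)
      if (node == s_node) next              # group clade is the whole tree
      h <- parent[node]
      if (h == 0) next
      sib <- setdiff(sets[[h]], sets[[node]])
      sis_x <- sib[cls[tips[sib]] == "neoX"]
      if (length(sis_x) == 0) next
      s_to_h <- dn[s_node, h]
      ht_x <- mean(dn[h, sis_x])
      ht_y <- mean(dn[h, g_idx])
      recs[[length(recs) + 1L]] <- data.table::data.table(
        window = w, start = tr$start, end = tr$end, group = g,
        s_to_h = s_to_h, h_to_tip_neoX = ht_x, h_to_tip_neoY = ht_y,
        fraction = ht_x / (s_to_h + ht_x))
    }
  }
  if (length(recs) == 0) {
    warning("no eligible windows")
    return(list(records = data.table::data.table(),
                estimates = data.table::data.table(
                  group = y_groups, median_s_to_h = NA_real_,
                  median_h_to_tip = NA_real_, median_h_to_tip_neoY = NA_real_,
                  normalized_fraction = NA_real_, age = NA_real_,
                  ci_lo = NA_real_, ci_hi = NA_real_, n_windows = 0L)))
  }
  records <- data.table::rbindlist(recs)
  set.seed(seed)
  est <- records[, {
    f <- fraction
    bmed <- if (length(f) >= 2 && boot > 0)
      vapply(seq_len(boot), function(b)
        stats::median(f[sample.int(length(f), replace = TRUE)]), numeric(1))
    else stats::median(f)
    ci <- stats::quantile(bmed, c(0.025, 0.975), names = FALSE)
    .(median_s_to_h = stats::median(s_to_h),
      median_h_to_tip = stats::median(h_to_tip_neoX),
      median_h_to_tip_neoY = stats::median(h_to_tip_neoY),
      normalized_fraction = stats::median(f),
      age = age_from_fraction(stats::median(f), species_split_kya),
      ci_lo = age_from_fraction(ci[1], species_split_kya),
      ci_hi = age_from_fraction(ci[2], species_split_kya),
      n_windows = .N)
  }, by = group]
  list(records = records, estimates = est[order(group)])
}
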