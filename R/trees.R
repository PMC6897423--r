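#' Infer a rooted window tree
#'
#' The internal method is neighbor-joining (via [ape::nj()]) on pairwise
#' Jukes–Cantor distances with IUPAC ambiguities scored as partial matches
#' (see [alignment_distances()]); negative NJ branch lengths are clamped to
#' zero and the tree is rooted on the designated outgroup. The external
#' method parses a user-supplied newick tree (e.g. a maximum-likelihood tree
#' built elsewhere) and roots it the same way; downstream classification is
#' identical for both. Alignments with no variable sites yield a star tree
#' flagged `zero_variation` and are excluded from classification.
#'
#' @param aln A `window_alignment` (internal method) or `NULL`.
#' @param method `"internal_nj"` or `"external_newick"`.
#' @param outgroup Character vector of outgroup tip labels (>= 1 present).
#' @param newick Newick string or file path (external method).
#' @param window Optional `c(start, end)` bp annotation for external trees.
#' @return `window_tree` object: list(`tree` (ape phylo, rooted), `start`,
#'   `end`, `zero_variation`).
#' @export
infer_tree <- function(aln = NULL, method = c("internal_nj", "external_newick"),
                       outgroup, newick = NULL, window = NULL) {
  method <- match.arg(method)
  if (method == "internal_nj") {
    stopifnot(inherits(aln, "window_alignment"))
    tips <- colnames(aln$mat)
    if (length(tips) < 4) stop("need >= 4 tips")
    if (!any(outgroup %in% tips)) stop("outgroup not present")
    if (aln$zero_variation) {
      star <- ape::read.tree(text = paste0("(", paste(tips, collapse = ","), ");"))
      star$edge.length <- rep(0, nrow(star$edge))
      return(structure(list(tree = star, start = aln$start, end = aln$end,
                            zero_variation = TRUE), class = "window_tree"))
    }
    d <- alignment_distances(aln)
    phy <- ape::nj(d)
    phy$edge.length[phy$edge.length < 0] <- 0
    phy <- root_on_outgroup(phy, intersect(outgroup, tips))
    structure(list(tree = phy, start = aln$start, end = aln$end,
                   zero_variation = FALSE), class = "window_tree")
  } else {
    phy <- if (file.exists(newick %||% "")) ape::read.tree(newick)
           else ape::read.tree(text = newick)
    if (ape::Ntip(phy) < 4) stop("need >= 4 tips")
    if (!any(outgroup %in% phy$tip.label)) stop("outgroup not present")
    phy <- root_on_outgroup(phy, intersect(outgroup, phy$tip.label))
    structure(list(tree = phy,
                   start = if (is.null(window)) NA else window[1],
                   end = if (is.null(window)) NA else window[2],
                   zero_variation = FALSE), class = "window_tree")
  }
}

root_on_outgroup <- function(phy, outgroup) {
  rooted <- try(ape::root(phy, outgroup = outgroup, resolve.root = TRUE),
                silent = TRUE)
  if (inherits(rooted, "try-error"))   # outgroup not monophyletic: root on one tip
    rooted <- ape::root(phy, outgroup = outgroup[1], resolve.root = TRUE)
  # Pin the root at the ingroup end of the junction edge: the whole edge
  # length goes to the outgroup-side child, so the root node (the s node in
  # dating) sits where the outgroup branch meets the ingroup subtree.
  nt <- ape::Ntip(rooted)
  kid_edges <- which(rooted$edge[, 1] == nt + 1L)
  if (length(kid_edges) == 2 && !is.null(rooted$edge.length)) {
    sets <- .node_tipsets(rooted)
    og_idx <- match(intersect(outgroup, rooted$tip.label), rooted$tip.label)
    has_og <- vapply(rooted$edge[kid_edges, 2],
                     function(n) any(sets[[n]] %in% og_idx), logical(1))
    if (sum(has_og) == 1) {
      rooted$edge.length[kid_edges[has_og]] <-
        rooted$edge.length[kid_edges[has_og]] +
        rooted$edge.length[kid_edges[!has_og]]
      rooted$edge.length[kid_edges[!has_og]] <- 0
    }
  }
  rooted
}

# tip index sets per node (tips and internals), by postorder accumulation
.node_tipsets <- function(phy) {
  nt <- ape::Ntip(phy)
  nn <- phy$Nnode
  sets <- vector("list", nt + nn)
  for (i in seq_len(nt)) sets[[i]] <- i
  edge <- phy$edge[ape::postorder(phy), , drop = FALSE]
  for (e in seq_len(nrow(edge)))
    sets[[edge[e, 1]]] <- c(sets[[edge[e, 1]]], sets[[edge[e, 2]]])
  lapply(sets, sort)
}

#' Count maximal exclusively-neo-Y clades
#'
#' Number of clades (including single tips) whose tip set consists only of
#' neo-Y tips and whose parent clade does not; a paraphyletic scatter of k
#' neo-Y singletons counts k.
#'
#' @param tree An ape `phylo` or a `window_tree`.
#' @param y_tips Character vector of neo-Y tip labels.
#' @return Integer count; the maximal clades' tip sets are attached as
#'   attribute `"members"`.
#' @export
count_neoY_clades <- function(tree, y_tips) {
  phy <- if (inherits(tree, "window_tree")) tree$tree else tree
  nt <- ape::Ntip(phy)
  y_idx <- match(intersect(y_tips, phy$tip.label), phy$tip.label)
  if (length(y_idx) == 0) return(structure(0L, members = list()))
  sets <- .node_tipsets(phy)
  is_y_only <- vapply(sets, function(s) all(s %in% y_idx), logical(1))
  parent <- integer(nt + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- nt + 1L
  maximal <- which(is_y_only &
                   (seq_along(sets) == root | !is_y_only[pmax(parent, 1L)]))
  members <- lapply(maximal, function(n) sort(phy$tip.label[sets[[n]]]))
  structure(length(maximal), members = members)
}

#' Classify the topology of a window tree
#'
#' Computes monophyly flags for the pooled neo-Ys, each Y group, and each
#' pair of Y groups (monophyletic to the exclusion of the remaining
#' groups); the placement of a monophyletic neo-Y clade from its sister
#' clade's composition; and whether the two species sort into distinct
#' clades (required for s-node dating).
#'
#' Placement: `sister_neoX` when the sister subtree holds all neo-X tips,
#' `within_neoX` when it holds a proper non-empty subset of them (the neo-Y
#' clade is nested among neo-Xs); `sister_chr3`/`within_chr3` analogously;
#' otherwise `unsorted`.
#'
#' @param tree A `window_tree` (or ape `phylo`).
#' @param groups Named character vector: tip label -> class, where class is
#'   `"neoX"`, `"chr3"`, or a Y-group name (anything else).
#' @return `topology_class` list of flags (see Details).
#' @export
classify_topology <- function(tree, groups) {
  phy <- if (inherits(tree, "window_tree")) tree$tree else tree
  zero_var <- inherits(tree, "window_tree") && isTRUE(tree$zero_variation)
  tips <- phy$tip.label
  if (!all(tips %in% names(groups))) stop("unassigned tip label: ",
      paste(setdiff(tips, names(groups)), collapse = ", "))
  cls <- groups[tips]
  x_tips <- tips[cls == "neoX"]
  o_tips <- tips[cls == "chr3"]
  y_groups <- sort(setdiff(unique(cls), c("neoX", "chr3")))
  y_tips <- tips[!cls %in% c("neoX", "chr3")]

  mono <- function(t) length(t) > 0 &&
    (length(t) == 1 || ape::is.monophyletic(phy, t))
  neoY_mono <- mono(y_tips)
  per_group <- vapply(y_groups, function(g) mono(tips[cls == g]), logical(1))
  pair_mono <- list()
  if (length(y_groups) >= 3) {
    for (i in seq_len(length(y_groups) - 1)) for (j in (i + 1):length(y_groups)) {
      key <- paste(y_groups[i], y_groups[j], sep = "+")
      pair_mono[[key]] <- mono(tips[cls %in% y_groups[c(i, j)]])
    }
  }
  species_sorted <- !zero_var && length(o_tips) > 0 &&
    mono(c(x_tips, y_tips)) && mono(o_tips)

  placement <- "unsorted"
  if (!zero_var && neoY_mono && length(y_tips) > 0) {
    sets <- .node_tipsets(phy)
    nt <- ape::Ntip(phy)
    y_idx <- match(y_tips, tips)
    node <- if (length(y_idx) == 1) y_idx else ape::getMRCA(phy, y_tips)
    parent <- integer(nt + phy$Nnode)
    parent[phy$edge[, 2]] <- phy$edge[, 1]
    root <- nt + 1L
    if (node != root) {
      sib <- setdiff(sets[[parent[node]]], sets[[node]])
      sib_cls <- unique(cls[tips[sib]])
      if (length(sib) > 0 && identical(sib_cls, "neoX")) {
        placement <- if (setequal(tips[sib], x_tips)) "sister_neoX" else "within_neoX"
      } else if (length(sib) > 0 && identical(sib_cls, "chr3")) {
        placement <- if (setequal(tips[sib], o_tips)) "sister_chr3" else "within_chr3"
      }
    }
  }
  structure(list(
    neoY_monophyletic = neoY_mono,
    neoY_paraphyletic = !neoY_mono && length(y_tips) >= 2,
    group_monophyletic = per_group,
    pair_monophyletic = pair_mono,
    placement = placement,
    species_sorted = species_sorted,
    zero_variation = zero_var,
    n_neoY_clades = as.integer(count_neoY_clades(phy, y_tips)),
    start = if (inherits(tree, "window_tree")) tree$start else NA,
    end = if (inherits(tree, "window_tree")) tree$end else NA
  ), class = "topology_class")
}
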