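test_that("pseudo-references substitute alleles and IUPAC-code heterozygotes", {
  ref <- strsplit("ACGTACGTAC", "")[[1]]
  gt <- data.frame(pos = c(2, 5, 7, 9),
                   sample = "s1",
                   a1 = c("G", "A", "A", NA),
                   a2 = c("G", "G", "A", NA))
  prefs <- build_pseudoreferences(ref, genotypes = gt)
  s <- pseudoref_sequence(prefs, "s1")
  expect_equal(substr(s, 2, 2), "G")     # hom alt
  expect_equal(substr(s, 5, 5), "R")     # A/G het
  expect_equal(substr(s, 7, 7), "A")     # hom alt over ref G
  expect_equal(substr(s, 9, 9), "A")     # missing -> reference retained
  # no variants -> identity
  prefs0 <- build_pseudoreferences(ref, genotypes = gt[0, ])
  expect_error(pseudoref_sequence(prefs0, "s1"), "unknown sample")
  # haploid path: MISSING masked to N
  ph <- build_pseudoreferences(ref, haploid = data.frame(
    pos = c(1, 3), sample = "y", allele = c("T", NA)))
  expect_equal(substr(pseudoref_sequence(ph, "y"), 1, 3), "TCN")
  expect_error(build_pseudoreferences(ref, genotypes = transform(gt, pos = 99)),
               "outside")
})

test_that("window slicing is exact arithmetic and reassembles the sequence", {
  set.seed(8)
  L <- 1000
  ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  gt <- data.frame(pos = sort(sample(1:L, 30)),
                   sample = rep(c("a", "b"), each = 15))
  gt$a1 <- sample(c("A", "C"), 30, replace = TRUE); gt$a2 <- gt$a1
  prefs <- build_pseudoreferences(ref, genotypes = gt)
  alns <- window_alignments(prefs, window = 200)
  expect_length(alns, 5)
  expect_equal(vapply(alns, `[[`, numeric(1), "start"), seq(0, 800, 200))
  # truncated final window
  alns2 <- window_alignments(prefs, window = 300)
  expect_equal(alns2[[4]]$end - alns2[[4]]$start, 100)
  # slicing then concatenating reconstructs the pseudo-reference
  for (s in c("a", "b")) {
    rebuilt <- paste(vapply(alns, function(a)
      alignment_sequences(a, prefs$ref)[[s]], character(1)), collapse = "")
    expect_identical(rebuilt, pseudoref_sequence(prefs, s))
  }
  # all-identical window flagged zero-variation, star tree downstream
  df0 <- data.frame(pos = integer(0), base = character(0))
  prefs1 <- build_pseudoreferences(ref)
  prefs1$variants <- list(a = df0, b = df0, c = df0, d = df0)
  aln0 <- window_alignments(prefs1, window = 1000)[[1]]
  expect_true(aln0$zero_variation)
  tr0 <- infer_tree(aln0, outgroup = "d")
  expect_true(tr0$zero_variation)
  expect_equal(ape::Ntip(tr0$tree), 4)
  expect_true(all(tr0$tree$edge.length == 0))
})

test_that("IUPAC-aware distances score partial matches as half", {
  ref <- rep("A", 100)
  prefs <- build_pseudoreferences(ref, haploid = data.frame(
    pos = rep(1:4, 4), sample = rep(c("w", "x", "y", "z"), each = 4),
    allele = c("A", "A", "A", "A",  "G", "G", "A", "A",
               "A", "A", "A", "A",  "T", "T", "T", "T")))
  aln <- window_alignments(prefs, window = 100)[[1]]
  # add a het (R) by hand at site 1 for sample y
  aln$mat[1, "y"] <- "R"
  d <- as.matrix(alignment_distances(aln, correction = "none"))
  expect_equal(d["w", "x"], 2 / 100)          # two full mismatches
  expect_equal(d["w", "y"], 0.5 / 100)        # A vs R = half match
  expect_equal(d["x", "y"], 1.5 / 100)        # G vs R half, G vs A full
  # JC correction is monotone and defined here
  dj <- as.matrix(alignment_distances(aln))
  expect_true(all(dj >= d - 1e-12))
  # saturation falls back with a warning
  sat <- aln
  sat$mat <- matrix(c(rep("A", 80), rep("G", 80),
                      rep("C", 80), rep("T", 80)), ncol = 4,
                    dimnames = list(NULL, c("w", "x", "y", "z")))
  sat$pos <- 1:80
  expect_warning(alignment_distances(sat), "satur")
})

test_that("NJ recovers additive quartets against the least-squares oracle", {
  # the spec's fixed example first
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 2
  d["c", "d"] <- d["d", "c"] <- 2
  d[cbind(c("a", "a", "b", "b"), c("c", "d", "c", "d"))] <- 6
  d[cbind(c("c", "d", "c", "d"), c("a", "a", "b", "b"))] <- 6
  phy <- ape::nj(as.dist(d))
  expect_true(ape::is.monophyletic(ape::unroot(phy), c("a", "b")))
  expect_equal(ls_best_quartet(d), "b")
  # 200 random additive instances
  set.seed(99)
  hits <- 0
  for (i in 1:200) {
    bl <- runif(5, 0.05, 1)   # a,b,c,d terminal + internal
    dm <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    dm["a", "b"] <- bl[1] + bl[2]
    dm["a", "c"] <- bl[1] + bl[5] + bl[3]
    dm["a", "d"] <- bl[1] + bl[5] + bl[4]
    dm["b", "c"] <- bl[2] + bl[5] + bl[3]
    dm["b", "d"] <- bl[2] + bl[5] + bl[4]
    dm["c", "d"] <- bl[3] + bl[4]
    dm <- dm + t(dm)
    phy <- ape::nj(as.dist(dm))
    ok_nj <- ape::is.monophyletic(ape::unroot(phy), c("a", "b"))
    hits <- hits + (ok_nj && ls_best_quartet(dm) == "b")
  }
  expect_equal(hits, 200)
})

test_that("infer_tree roots on the outgroup and external newick is equivalent", {
  bun <- default_cohort_bundle()
  tr <- bun$trees[[3]]
  expect_s3_class(tr$tree, "phylo")
  expect_true(ape::is.rooted(tr$tree))
  # external path: re-read the same topology from newick
  nwk <- ape::write.tree(tr$tree)
  tr2 <- infer_tree(method = "external_newick", newick = nwk,
                    outgroup = c("out_1", "out_2"), window = c(tr$start, tr$end))
  tc1 <- classify_topology(tr, bun$groups)
  tc2 <- classify_topology(tr2, bun$groups)
  expect_equal(tc1$group_monophyletic, tc2$group_monophyletic)
  expect_equal(tc1$placement, tc2$placement)
  expect_error(infer_tree(method = "external_newick",
                          newick = "((a,b),(c,d));", outgroup = "zz"),
               "outgroup")
})

test_that("topology classification matches the worked newick cases", {
  grp <- c(Y1a = "Y1", Y1b = "Y1", Xa = "neoX", Xb = "neoX",
           N1 = "chr3", N2 = "chr3")
  t1 <- classify_topology(ape::read.tree(text = "((Y1a,Y1b),(Xa,Xb));"),
                          grp[c(1, 2, 3, 4)])
  expect_true(t1$neoY_monophyletic)
  expect_false(t1$neoY_paraphyletic)
  expect_equal(t1$placement, "sister_neoX")
  t2 <- classify_topology(ape::read.tree(text = "((Y1a,Xa),(Y1b,Xb));"),
                          grp[c(1, 3, 2, 4)])
  expect_true(t2$neoY_paraphyletic)
  expect_false(t2$neoY_monophyletic)
  t3 <- classify_topology(
    ape::read.tree(text = "(((Y1a,Y1b),(N1,N2)),(Xa,Xb));"), grp)
  expect_true(t3$neoY_monophyletic)
  expect_equal(t3$placement, "sister_chr3")
  expect_true(t3$species_sorted == FALSE)  # neo-Ys sit with Chr.3
  t4 <- classify_topology(
    ape::read.tree(text = "((((Y1a,Y1b),Xa),Xb),(N1,N2));"), grp)
  expect_equal(t4$placement, "within_neoX")
  expect_true(t4$species_sorted)
  expect_error(classify_topology(ape::read.tree(text = "((Y1a,Zq),(Xa,Xb));"),
                                 grp), "unassigned")
})

test_that("classification is invariant to tip order and node rotation", {
  grp <- c(Y1a = "Y1", Y1b = "Y1", Y2a = "Y2", Xa = "neoX", Xb = "neoX",
           N1 = "chr3")
  a <- classify_topology(
    ape::read.tree(text = "(((Y1a,Y1b),(Y2a,Xa)),(Xb,N1));"), grp)
  b <- classify_topology(
    ape::read.tree(text = "((N1,Xb),((Xa,Y2a),(Y1b,Y1a)));"), grp)
  for (f in c("neoY_monophyletic", "neoY_paraphyletic", "placement"))
    expect_equal(a[[f]], b[[f]], label = f)
  expect_equal(a$group_monophyletic, b$group_monophyletic)
})

test_that("simulated windows classify as the generating structure", {
  bun <- default_cohort_bundle()
  tops <- bun$topologies
  # nasuta block: all neo-Ys one clade, species not sorted
  expect_equal(tops[[1]]$n_neoY_clades, 1L)
  expect_false(tops[[1]]$species_sorted)
  # non-block windows are species sorted with per-group monophyly
  for (w in 2:10) {
    expect_true(tops[[w]]$species_sorted, label = paste("window", w))
    expect_true(all(unlist(tops[[w]]$group_monophyletic)),
                label = paste("window", w))
  }
  # telomeric end: all neo-Ys merge into one clade among the neo-Xs
  expect_equal(tops[[10]]$n_neoY_clades, 1L)
  expect_true(tops[[10]]$neoY_monophyletic)
  expect_true(tops[[10]]$placement %in% c("within_neoX", "sister_neoX"))
})
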