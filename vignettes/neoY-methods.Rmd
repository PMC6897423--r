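---
title: "Models and methods behind neoYtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neoYtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A neo-Y chromosome is a former autosome that became male-limited through a
Y–autosome fusion. Once males stop recombining, each neo-Y lineage evolves
clonally: it diverges from its neo-X homolog, accumulates substitutions,
indels and frameshifts, and its genes begin to be down-regulated relative to
their neo-X alleles. `neoYtools` packages the computational steps of such an
analysis: inferring haploid neo-Y genotypes from paired male/female diploid
calls, windowed population-genetic statistics, window phylogenies with
topology classification, haplotype-block painting, branch-ratio dating of
recombination cessation, DNA-corrected allele-specific expression, coding
degeneration annotation with Ka/Ks, and a permutation test for tissue-bias
enrichment.

Because females carry two neo-X copies while males carry one neo-X and one
neo-Y, mapping males to a female-derived assembly shows the neo-Y as the
heterozygous allele: at a site homozygous in the female and heterozygous in
the male, the male allele not seen in the female is the neo-Y genotype.
Sites heterozygous in the female are unresolvable and left missing. This
single rule, plus depth (≥ 5x) and genotype-quality (≥ 20) filters, drives
the genotyping module.

# The synthetic cohort: a stated world

Real cohorts of this kind are tens of samples at ~50 Mb; nothing in the
method depends on that scale, so the generator emulates the same structure
on a 2 Mb chromosome that runs end-to-end in seconds. The stated world:

* **Species split** `T_s = 250` kya separates the ingroup from the outgroup
  (Chr.3 of the sister species). Time is measured in kyr with a fixed
  substitution rate `mu` per bp per kyr (default `4e-6`, chosen so that
  `mu * 107 kyr ≈ 4.3e-4` substitutions/site matches the magnitude of the
  branch lengths the method is designed to measure). No generation-time
  conversion is applied.
* **Neo-X standing diversity** is a star genealogy: each of `n_neoX`
  haplotypes mutates independently from a common ancestor for
  `theta/(2*mu)` kyr. The default `theta = 2e-3` places that ancestor at
  the species split. This is deliberate: in gene trees, ingroup lineages
  coalesce at or above the split, and the branch-ratio dating method reads
  the s node (species MRCA) as the top of the ingroup. A shallower pool
  would bias the normalized fractions upward; a full coalescent would add
  realism (variable coalescence depths, a site-frequency spectrum) the
  mosaic analysis does not consume.
* **Neo-Y groups** are recombinant mosaics: each group's founder copies a
  donor neo-X lineage per segment, switching at configured breakpoints; at
  the group's `recomb_stop_kya` the founder freezes and the group's strains
  descend clonally, receiving Poisson(`mu * L * stop`) group-fixed
  substitutions and Poisson(`indel_rate * L * stop`) indels. Default stop
  times are 106.8, 89.6 and 135.2 kya for Y1 (3 strains), Y2 (2) and Y3
  (3).
* **Two unsampled ancestral donors** create the clade structure seen in
  windowed trees of real data: `ancY`, the original fusion haplotype,
  donates every group's telomeric-end segment (so all neo-Ys merge into one
  exclusively-neo-Y clade there), and `ancN`, an outgroup-derived haplotype
  carried by every neo-Y across the centromere-proximal block. `ancN`
  branches off a sampled outgroup lineage midway between the oldest stop
  time and the outgroup crown (default depth 200 kyr), so block windows
  place the neo-Ys *inside* the outgroup diversity and species sorting
  fails there — which is exactly why such windows must be excluded from
  dating.
* **Infinite sites**: all substitution positions are drawn once, globally,
  without replacement, so every variant belongs to exactly one truth
  category and truth-set comparisons are exact.
* **Diploid encoding**: females are `neoX/neoX` (homozygous for the strain
  haplotype with probability `inbreeding`, default 0.7), males are
  `neoX/neoY`, outgroup strains `Chr3/Chr3`. A small fraction of
  site-by-sample calls (default 1%) gets low depth or quality to exercise
  the filters.
* **Counts are Poisson per allele.** DNA has a 1:1 expected ratio; RNA
  splits `2 * rna_depth` between alleles as `2r/(1+r) : 2/(1+r)` for true
  ratio `r`, mirroring coverage-ratio read simulations (10x:5x = 2-fold).
  This is the simplest model with the right mean ratio; it has no
  overdispersion, so a green recovery test establishes correctness of the
  estimator, not robustness to biological noise.
* **Tissue profiles**: biased genes express 100/30/0... across tissues
  (tau ≈ 0.94 at zero noise), unbiased genes uniformly, with multiplicative
  lognormal noise.

What the generator does *not* emulate: linked selection, realistic
recombination maps, the site-frequency spectrum, read-level errors,
reference mapping bias (counts are generated per allele directly), and
overdispersed expression. Green tests therefore establish algorithmic
correctness against the stated model, not performance on real libraries.

# Windowed statistics

Per-site diversity uses the unbiased pairwise estimator
`sum_a c_a (k - c_a) / 2 / C(k,2)` over non-missing haplotypes; windows sum
sites and divide by the full window span in bp (the convention of the
common VCF windowing tools), so uncalled and monomorphic bases count as
zero differences rather than shrinking the denominator. F_ST defaults to
the Weir–Cockerham ratio-of-sums estimator reduced to haploid form (no
heterozygosity terms), with the Hudson `1 - Hw/Hb` estimator as a
cross-check; the estimator may dip slightly below zero and is reported
unclipped. `Da = Dxy - (pi_X + pi_Y)/2` per window, negative values kept so
that downstream comparisons are unbiased.

# Window trees, classification, painting, dating

Pseudo-references substitute each sample's alleles into the reference
(IUPAC codes at heterozygous sites; missing genotypes keep the reference
base, matching the behaviour of the standard pseudo-reference tool — except
for inferred neo-Y haplotypes, where missing calls are masked to `N`
because those sites were removed from the analysis). Window alignments are
coordinate slices — the sequences are positionally homologous by
construction, so no realignment is performed; they are stored sparsely
(variant columns only) and materialised on demand.

The internal tree method is neighbor-joining on Jukes–Cantor distances with
IUPAC ambiguities scored as `|intersection| / max(set sizes)` (a base
against a two-base code sharing it counts half a match); `N` and gaps drop
out pairwise. Saturated pairs (p ≥ 0.75) fall back to the p-distance with a
warning. NJ is delegated to `ape::nj` (deterministic for a given input
order; we do not re-implement its tie-breaking), negative branch lengths
are clamped to zero, and the tree is rooted on the outgroup. A maximum
likelihood tree is not needed: downstream statistics consume only topology
and relative branch lengths, which NJ preserves at these divergences, and
externally built newick trees are first-class inputs for exact
reproduction. The default window is 200 kb, non-overlapping: the step size
is not dictated by anything in the method, and overlap would
pseudo-replicate windows in the dating medians.

One numerical choice deserves a note: after outgroup rooting, the junction
edge is assigned entirely to the outgroup-side child, pinning the root — the
s node used in dating — at the point where the outgroup branch meets the
ingroup subtree. Left to the rooting function's default, part of the
outgroup stem leaks into every s-to-h path and inflates it.

Topology classification computes pooled/per-group/pairwise monophyly of the
neo-Ys, the placement of a monophyletic neo-Y clade from its sister
subtree's composition (pure neo-X sister: `sister_neoX` if it holds all
neo-X tips, `within_neoX` if a proper subset; analogously for Chr.3), and
`species_sorted` — ingroup and outgroup each forming clean clades — which
gates dating.

Painting assigns one label per maximal exclusively-neo-Y clade per window,
matches labels across adjacent windows by maximal member-set overlap (ties
toward the left window's smaller label), and smooths single-window
interruptions whose two flanks agree. Breakpoints are label transitions,
reported at the boundary between the differing windows; since a transition
is only localised to that boundary, recovery is assessed to ±1 window.

Dating, per eligible window and group: s = MRCA of all tips; h = parent of
the group's clade; `s_to_h` the path between them; `h_to_tip` averaged over
the neo-X tips of the clade's sister subtree (the neo-Y variant is also
reported). The normalized fraction `h_to_tip / (s_to_h + h_to_tip)` is
computed per window and the *median of ratios* is taken — printed column
medians do not compose into a printed normalized value, so per-window
normalization is the only self-consistent reading. Age = fraction x the
species-split age (250 kya by default); the 95% CI is a seeded
nonparametric bootstrap (1000 reps) over windows, a choice we make
explicitly since no CI construction is dictated by the method itself.
Windows where a group's clade has no neo-X sister tips (it hangs from an
unsampled ancestral lineage) contribute no record; in mixed regions the
median across windows absorbs the occasional fraction-near-1 window where
a group's nearest sampled neo-X ancestor is the species split itself. The
`restrict` argument reproduces the practice of dating all groups on a
common interval.

# Allele-specific expression

The corrected fold difference divides the RNA fold (neo-X/neo-Y) by the DNA
fold, cancelling residual mapping bias that survives dual-reference
counting; genes with fewer than 5 reads in both RNA alleles are removed.
Genes passing the filter but containing a zero cell get the
Haldane–Anscombe +0.5 on all four cells for the fold only. Each gene is
tested with a two-sided Fisher's exact test on `[[rna_x, rna_y], [dna_x,
dna_y]]` — the natural 2x2 given that the DNA is the bias control — with
Benjamini–Hochberg correction, and the chromosome-level excess of neo-X-
over neo-Y-biased genes is an exact binomial test against 0.5. The
`validate_fold_recovery()` loop regenerates counts at configured coverage
ratios and reports median per-gene corrected folds; with Poisson counts at
depth 200 the median is within a few hundredths of the true ratio.

ChIP enrichment normalises IP and input site counts by each library's
median autosomal coverage, takes IP/input per distinguishing site, averages
sites within 50 kb windows, and reports the standard error across replicate
libraries; zero-input sites are skipped and counted.

# Degeneration

SNP effects are classified by single-variant codon substitution against the
reference CDS on the transcript strand (no haplotype-aware codon
reconstruction — co-occurring variants in one codon are classified one at a
time, a simplification that matters only at high density). Indels in CDS
are frameshifts when their length is not a multiple of 3, in-frame
otherwise; outside CDS they are near-gene within 500 bp, else intergenic.

Ka/Ks uses Nei–Gojobori (1986): per-codon expected synonymous site counts
averaged over both sequences, pathway-averaged difference counting for
multi-hit codons (pathways through stop codons are excluded unless every
pathway hits one), and Jukes–Cantor correction. Mutations *to* stop codons
count as nonsynonymous in the site counts. The original analysis used a
gamma-corrected maximum-likelihood estimator from an external program; NG86
is substituted deliberately: the pipeline only requires an estimator
monotone in divergence, and NG86 admits an exact brute-force oracle
(exhaustive pathway enumeration) that pins the implementation down in
tests. Identical allele pairs are excluded before estimation, and the ratio
is undefined when Ks = 0.

# Tissue enrichment

`tau = sum_i (1 - x_i/x_max) / (N - 1)`; genes with tau > 0.5 are
tissue-biased and assigned their two highest-expression tissues. The
enrichment null makes two independent draws without replacement — the
tissue-biased count from the Chr.3 universe and the focal count from the
filtered universe — and records the overlap. We assume the filtered
universe is nested in the Chr.3 universe (the filter only removes genes),
and realise the two draws exactly as a two-stage hypergeometric sample per
replicate, which is distribution-identical to drawing the index sets and
intersecting but vectorises to 100,000 replicates instantly. Expected count
= median of the null; p = `2 * min(P(null >= obs), P(null <= obs))` capped
at 1 (the percentile reading made two-sided); the display statistic is
`sign(obs - exp) * (obs - exp)^2 / max(exp, 1)`, a signed chi-square-style
cell statistic whose exact published form is not specified anywhere we
could pin down.

# Known limitations

* The generator's star genealogies make every neo-X equidistant; NJ
  resolutions among them are arbitrary (harmless downstream, since no
  statistic reads neo-X internal structure).
* Clonal groups are literally identical (within-group diversity zero);
  real groups retain low diversity, so within-group π tests here only
  check the degenerate limit.
* The Fisher 2x2 construction and the two-sided percentile p are the
  package's own choices among unstated alternatives; both are parameters
  of record in this vignette rather than switches.
* `read_genotype_vcf` handles SNVs only; indel genotypes travel through the
  dedicated indel tables.
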