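test_that("corrected fold difference matches the worked arithmetic", {
  expect_equal(corrected_fold_difference(100, 50, 60, 60), 2)
  expect_equal(corrected_fold_difference(100, 50, 100, 50), 1)
  expect_equal(corrected_fold_difference(30, 10, 20, 10), 1.5)
  # vectorised
  expect_equal(corrected_fold_difference(c(100, 30), c(50, 10),
                                         c(60, 20), c(60, 10)), c(2, 1.5))
  # all-zero record undefined
  expect_true(is.na(corrected_fold_difference(0, 0, 0, 0)))
  # single zero cell gets the +0.5 continuity correction, stays finite
  f <- corrected_fold_difference(10, 0, 5, 5)
  expect_true(is.finite(f) && f > 1)
  expect_error(corrected_fold_difference(-1, 1, 1, 1), ">= 0")
})

test_that("corrected fold is scale-invariant and antisymmetric under swap", {
  set.seed(4)
  for (i in 1:20) {
    cnt <- rpois(4, 50) + 1
    f <- corrected_fold_difference(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(corrected_fold_difference(3 * cnt[1], 3 * cnt[2],
                                           5 * cnt[3], 5 * cnt[4]), f)
    swapped <- corrected_fold_difference(cnt[2], cnt[1], cnt[4], cnt[3])
    expect_equal(swapped, 1 / f, tolerance = 1e-12)
  }
})

test_that("allele-bias testing calls directions and filters low counts", {
  rec <- data.frame(gene = c("up", "flat", "low", "down"),
                    rna_x = c(500, 50, 3, 100),
                    rna_y = c(100, 50, 2, 400),
                    dna_x = c(300, 50, 100, 300),
                    dna_y = c(300, 50, 100, 300))
  res <- test_allele_bias(rec)
  expect_equal(res$summary$n_filtered, 1L)          # "low" dropped (<5 both)
  expect_false("low" %in% res$records$gene)
  expect_equal(res$records[gene == "up"]$bias_call, "neoX")
  expect_equal(res$records[gene == "down"]$bias_call, "neoY")
  expect_equal(res$records[gene == "flat"]$p_raw, 1)
  expect_equal(res$records[gene == "flat"]$bias_call, "none")
  # Fisher oracle: p for the 2x2 equals hypergeometric enumeration
  p_direct <- stats::fisher.test(matrix(c(500, 100, 300, 300), 2,
                                        byrow = TRUE))$p.value
  expect_equal(res$records[gene == "up"]$p_raw, p_direct)
  expect_true(all(res$records$p_fdr >= res$records$p_raw))
  expect_error(test_allele_bias(rec[0, ]), "empty")
})

test_that("BH calls nest with alpha and binomial summary matches Table-2 case", {
  set.seed(5)
  n <- 300
  rec <- data.frame(gene = paste0("g", 1:n),
                    rna_x = rpois(n, 100), rna_y = rpois(n, 100),
                    dna_x = rpois(n, 100), dna_y = rpois(n, 100))
  rec$rna_x[1:20] <- rpois(20, 220)   # a planted biased subset
  r1 <- test_allele_bias(rec, alpha_fdr = 0.01)
  r2 <- test_allele_bias(rec, alpha_fdr = 0.10)
  called1 <- r1$records$gene[r1$records$bias_call != "none"]
  called2 <- r2$records$gene[r2$records$bias_call != "none"]
  expect_true(all(called1 %in% called2))
  # 28 neo-X vs 9 neo-Y biased genes: exact binomial p < 0.01
  expect_lt(binomial_bias_summary(28, 9), 0.01)
  expect_equal(binomial_bias_summary(28, 9),
               stats::binom.test(28, 37, 0.5)$p.value)
})

test_that("type-I error of the per-gene Fisher test is calibrated", {
  cfg <- sim_config(n_genes = 2000, ase_ratios = 1, dna_depth = 200,
                    rna_depth = 200, seed = 17)
  cnt <- simulate_allele_counts(cfg)
  res <- test_allele_bias(cnt$records)
  frac <- mean(res$records$p_raw < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("fold recovery at the validation coverage ratios", {
  vr <- validate_fold_recovery(c(2, 1.25, 1), rna_depth = 300, dna_depth = 300,
                               n_genes = 1000, seed = 23)
  expect_lt(abs(vr$median_fold[1] - 2), 0.1)
  expect_gte(vr$median_fold[2], 1.2); expect_lte(vr$median_fold[2], 1.3)
  expect_gte(vr$median_fold[3], 0.97); expect_lte(vr$median_fold[3], 1.03)
  expect_warning(validate_fold_recovery(1, n_genes = 10, seed = 1), "unstable")
  expect_error(validate_fold_recovery(-1), "> 0")
})

test_that("ChIP window enrichment normalises by autosomal coverage", {
  ac <- data.frame(rep = rep(1:2, each = 2), role = rep(c("ip", "input"), 2),
                   median_cov = c(20, 10, 40, 20))
  sites <- expand.grid(pos = c(100, 200, 60000), allele = c("neoX", "neoY"),
                       rep = 1:2, stringsAsFactors = FALSE)
  ip <- transform(sites, count = ifelse(rep == 1, 40, 80))    # 2x autosomal
  input <- transform(sites, count = ifelse(rep == 1, 10, 20)) # 1x autosomal
  res <- chip_window_enrichment(ip, input, ac, window = 50000)
  expect_true(all(abs(res$windows$enrichment - 2) < 1e-12))
  expect_true(all(res$windows$se == 0))
  expect_equal(sort(unique(res$windows$start)), c(0, 50000))
  # zero-input sites are skipped and counted
  input0 <- input; input0$count[1] <- 0
  res0 <- chip_window_enrichment(ip, input0, ac, window = 50000)
  expect_equal(res0$n_skipped, 1L)
  expect_error(chip_window_enrichment(ip, input, transform(ac, median_cov = 0)),
               "> 0")
})

test_that("equal-enrichment neo-X/neo-Y tracks correlate under the null", {
  set.seed(31)
  pos <- sort(sample(1:1e6, 2000))
  base <- runif(2000, 0.5, 3)            # shared underlying enrichment profile
  grid <- expand.grid(pos = pos, allele = c("neoX", "neoY"), rep = 1:4,
                      stringsAsFactors = FALSE)
  grid$mu <- base[match(grid$pos, pos)]
  ip <- transform(grid, count = rpois(nrow(grid), 30 * mu))
  input <- transform(grid, count = rpois(nrow(grid), 30))
  ac <- expand.grid(rep = 1:4, role = c("ip", "input"))
  ac$median_cov <- 30
  res <- chip_window_enrichment(ip, input, ac, window = 50000)$windows
  wide <- data.table::dcast(res, start ~ allele, value.var = "enrichment")
  expect_gte(cor(wide$neoX, wide$neoY), 0.9)
  ratio <- median(wide$neoX / wide$neoY)
  expect_gte(ratio, 0.9); expect_lte(ratio, 1.1)
})
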