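# Small helper: simulated bin genotypes + phenotype with known QTL.
qtl_fixture <- function(n_lines = 200, pve = 0.2, qtl_pos = 30e6,
                        seed = 3, coverage = 2, epistasis = NULL,
                        effect = NULL, n_chrom = 2, len = 50e6) {
  d <- sim_dataset(n_lines = n_lines, n_chrom = n_chrom, len = len,
                   coverage = coverage, map_length = 0.7, seed = seed)
  a <- effect %||% skimbin::effect_for_pve(pve)
  qs <- qtl_spec(loci = data.frame(chrom = "chr1", pos = qtl_pos,
                                   effect = a),
                 epistasis = epistasis, sigma = 1)
  ph <- simulate_phenotypes(d$truth, qs, seed = seed)
  bg <- bin_matrix(d$calls, make_bins(d$genome))
  list(d = d, bg = bg, y = pool_phenotype(ph), qs = qs)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the LOD of a toy table equals a two-model regression oracle", {
  geno <- matrix(c("P1", "P1", "P1", "P1", "P2", "P2", "P2", "P2",
                   "P1", "P2", "P1", "P2", "P1", "P2", "P1", "P2"),
                 8, 2)
  rownames(geno) <- paste0("L", 1:8)
  bg <- toy_bin_genotypes(geno)
  y <- setNames(c(2.3, 1.9, 2.7, 2.1, -1.2, -0.8, -1.6, -0.7),
                paste0("L", 1:8))
  res <- single_marker_scan(bg, y, scan_config(min_lines = 5))
  # oracle: explicit lm fits, LOD = (n/2) log10(RSS0/RSS1)
  for (j in 1:2) {
    g <- ifelse(geno[, j] == "P1", 1, -1)
    rss1 <- sum(resid(lm(y ~ g))^2)
    rss0 <- sum(resid(lm(y ~ 1))^2)
    expect_equal(res$LOD[j], (8 / 2) * log10(rss0 / rss1),
                 tolerance = 1e-10)
    expect_equal(res$PVE[j], 1 - rss1 / rss0, tolerance = 1e-10)
    expect_equal(res$effect[j], unname(coef(lm(y ~ g))[2]),
                 tolerance = 1e-10)
  }
})

test_that("a perfect genotype-phenotype match caps the LOD", {
  geno <- matrix(rep(c("P1", "P2"), 15), 30, 1)
  rownames(geno) <- paste0("L", 1:30)
  bg <- toy_bin_genotypes(geno)
  y <- setNames(ifelse(geno[, 1] == "P1", 1, -1), rownames(geno))
  res <- single_marker_scan(bg, y, scan_config())
  expect_equal(res$LOD[1], 300)
  expect_equal(res$PVE[1], 1)
})

test_that("LOD is invariant to affine phenotype transforms", {
  fx <- qtl_fixture(n_lines = 80, seed = 11)
  r1 <- single_marker_scan(fx$bg, fx$y, scan_config())
  r2 <- single_marker_scan(fx$bg, 3.2 * fx$y - 17, scan_config())
  expect_equal(r1$LOD, r2$LOD, tolerance = 1e-10)
  expect_equal(r1$PVE, r2$PVE, tolerance = 1e-10)
})

test_that("relabeling the parents flips effect signs only", {
  fx <- qtl_fixture(n_lines = 80, seed = 13)
  bg2 <- fx$bg
  sw <- c(P1 = "P2", P2 = "P1", H = "H")
  bg2$geno[] <- sw[bg2$geno]
  r1 <- single_marker_scan(fx$bg, fx$y, scan_config())
  r2 <- single_marker_scan(bg2, fx$y, scan_config())
  expect_equal(r1$LOD, r2$LOD, tolerance = 1e-10)
  expect_equal(r1$effect, -r2$effect, tolerance = 1e-10)
})

test_that("degenerate phenotypes are rejected", {
  fx <- qtl_fixture(n_lines = 40, seed = 17)
  y0 <- fx$y
  y0[] <- 5
  expect_error(single_marker_scan(fx$bg, y0, scan_config()), "constant")
  expect_error(single_marker_scan(fx$bg, fx$y[1:5],
                                  scan_config()), "fewer")
})

test_that("the permutation threshold is the stated order statistic", {
  fx <- qtl_fixture(n_lines = 60, seed = 19)
  cfg <- scan_config(permutations = 100, alpha = 0.05, seed = 42)
  th1 <- permutation_threshold(fx$bg, fx$y, cfg)
  th2 <- permutation_threshold(fx$bg, fx$y, cfg)
  expect_identical(th1, th2)  # seeded determinism
  expect_equal(th1$threshold, sort(th1$max_lods)[95])
})

test_that("a strong additive QTL is detected at the right bin", {
  fx <- qtl_fixture(n_lines = 250, pve = 0.25, qtl_pos = 8e6, seed = 23)
  res <- single_marker_scan(fx$bg, fx$y, scan_config())
  th <- permutation_threshold(fx$bg, fx$y,
                              scan_config(permutations = 200, seed = 1))
  peak <- res[which.max(res$LOD)]
  expect_gt(peak$LOD, th$threshold)
  expect_equal(peak$chrom, "chr1")
  expect_lte(abs(peak$start + 5e5 - 8e6), 2e6)
  expect_true(peak$major)
})

test_that("epistasis scans report the interaction and its sign", {
  eff <- effect_for_pve(0.25)
  fx <- qtl_fixture(n_lines = 400, effect = 0,
                    epistasis = data.frame(chrom1 = "chr1", pos1 = 10e6,
                                           chrom2 = "chr2", pos2 = 40e6,
                                           effect = -eff),
                    seed = 29)
  cand <- c(fx$bg$bins[chrom == "chr1" & start == 10e6, bin],
            fx$bg$bins[chrom == "chr2" & start == 40e6, bin],
            fx$bg$bins[chrom == "chr1" & start == 44e6, bin])
  res <- epistasis_scan(fx$bg, fx$y, candidates = cand, scan_config())
  res <- res[res$skipped == FALSE, ]
  top <- res[which.max(res$int_LOD), ]
  expect_setequal(c(top$bin1, top$bin2), cand[1:2])
  expect_lt(top$gamma, 0)
})

test_that("collinear candidate pairs are skipped", {
  geno <- matrix(rep(rep(c("P1", "P2"), 25), 2), 50, 2)
  rownames(geno) <- paste0("L", 1:50)
  bg <- toy_bin_genotypes(geno)
  y <- setNames(rnorm(50), rownames(geno))
  res <- epistasis_scan(bg, y, candidates = bg$bins$bin,
                        scan_config(min_lines = 10))
  expect_true(all(res$skipped))
})

test_that("site association finds a Mendelian locus and controls nulls", {
  d <- sim_dataset(n_lines = 150, n_chrom = 1, len = 30e6,
                   density = 1 / 2e4, coverage = 0.1, seed = 31)
  imp <- impute_matrix(d$calls, d$key, impute_config())
  # scored 1/2/3 trait driven by one locus
  qs <- qtl_spec(loci = data.frame(chrom = "chr1", pos = 4e6, effect = 1),
                 sigma = 0.1, qualitative = TRUE)
  y <- pool_phenotype(simulate_phenotypes(d$truth, qs, seed = 31))
  cfg <- scan_config(subsample_frac = 0.5, seed = 7)
  res <- site_association_scan(imp$calls, y, cfg)
  peak <- res[which.min(res$p)]
  expect_lt(abs(peak$pos - 4e6), 1e6)
  expect_true(res[significant == TRUE, .N] > 0)
  # null phenotype: no discoveries at q <= 0.05 (typically)
  y0 <- setNames(rnorm(length(y)), names(y))
  res0 <- site_association_scan(imp$calls, y0, cfg)
  expect_lte(res0[significant == TRUE, .N], 2)
  # too-small subsamples are rejected
  expect_error(site_association_scan(imp$calls, y,
                                     scan_config(subsample_frac = 0.01)),
               "100")
})

test_that("full-site scans contain the subsample's hits", {
  d <- sim_dataset(n_lines = 80, n_chrom = 1, len = 20e6,
                   density = 1 / 2e4, coverage = 0.2, seed = 37)
  imp <- impute_matrix(d$calls, d$key, impute_config())
  qs <- qtl_spec(loci = data.frame(chrom = "chr1", pos = 5e6,
                                   effect = 2), sigma = 0.5)
  y <- pool_phenotype(simulate_phenotypes(d$truth, qs, seed = 37))
  sub <- site_association_scan(imp$calls, y,
                               scan_config(subsample_frac = 0.2, seed = 5))
  full <- site_association_scan(imp$calls, y,
                                scan_config(subsample_frac = 1, seed = 5))
  sig_sub <- sub[significant == TRUE, paste(chrom, pos)]
  sig_full <- full[significant == TRUE, paste(chrom, pos)]
  expect_true(all(sig_sub %in% sig_full))
})
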