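test_that("simulated parent key is segregating, sorted and reproducible", {
  g <- tiny_genome(n_chrom = 2)
  key1 <- simulate_parents(g, seed = 42)
  key2 <- simulate_parents(g, seed = 42)
  expect_identical(as.data.frame(key1), as.data.frame(key2))
  expect_true(all(key1$p1 != key1$p2))
  expect_true(all(key1$p1 %in% c("ref", "alt")))
  expect_false(any(duplicated(key1[, c("chrom", "pos")])))
  expect_false(is.unsorted(key1[chrom == "chr1", pos]))
  # Poisson placement: ~1000 sites per 10 Mb at 1/10 kb
  n1 <- nrow(key1[chrom == "chr1"])
  expect_gt(n1, 1000 - 4 * sqrt(1000))
  expect_lt(n1, 1000 + 4 * sqrt(1000))
  # wild-like parent matches the reference at most sites
  pp <- parent_allele_proportions(key1)
  expect_gt(pp[["p1_ref"]], pp[["p2_ref"]])
  expect_equal(pp[["p1_ref"]], 0.875, tolerance = 0.05)
})

test_that("degenerate genomes are rejected", {
  g <- genome_spec("chr1", 1e5, 1 / 1e5)  # ~1 expected site
  expect_error(simulate_parents(g, seed = 1), "degenerate")
})

test_that("truth blocks tile chromosomes and alternate labels", {
  d <- sim_dataset(n_lines = 15, seed = 3)
  blocks <- d$truth$blocks
  chk <- blocks[, {
    len <- d$genome$lengths[match(.BY$chrom, d$genome$chroms)]
    list(
      tiles = start[1] == 0 && abs(end[.N] - len) < 1e-6 &&
        all(abs(start[-1] - end[-.N]) < 1e-6),
      alternates = .N == 1 || all(label[-1] != label[-.N])
    )
  }, by = .(line, chrom)]
  expect_true(all(chk$tiles))
  expect_true(all(chk$alternates))
})

test_that("zero map length gives whole-chromosome blocks", {
  g <- tiny_genome()
  key <- simulate_parents(g, seed = 5)
  cfg <- sim_config(n_lines = 10, map_length = 0, seed = 5)
  truth <- simulate_ril_population(key, cfg)
  expect_true(all(truth$blocks[, .N, by = .(line, chrom)]$N == 1))
  expect_equal(nrow(truth$breakpoints), 0)
})

test_that("no crossover lands inside the recombination desert", {
  d <- sim_dataset(n_lines = 30, n_chrom = 1, len = 100e6, seed = 9)
  bp <- d$truth$breakpoints
  # desert_frac 0.5 centered at 50 Mb: (25, 75) Mb must be empty
  expect_equal(nrow(bp[pos > 25e6 & pos < 75e6]), 0)
})

test_that("mean breakpoints per line per chromosome approaches 2L", {
  # Haldane-Waddington: a selfed RIL accumulates 2L observable crossovers
  # per chromosome of map length L Morgans as generations grow
  g <- genome_spec("chr1", 100e6, 1 / 1e5)
  key <- simulate_parents(g, seed = 21)
  cfg <- sim_config(n_lines = 300, generations = 14, map_length = 1,
                    seed = 21)
  truth <- simulate_ril_population(key, cfg)
  per_line <- truth$breakpoints[is_crossover == TRUE, .N, by = line]
  counts <- rep(0, cfg$n_lines)
  counts[seq_len(nrow(per_line))] <- per_line$N
  m <- mean(counts)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(m - 2), 3 * se + 1e-9)
})

test_that("residual heterozygosity decays as (1/2)^(g-1)", {
  g <- tiny_genome(len = 50e6, density = 1 / 5e4)
  key <- simulate_parents(g, seed = 13)
  hets <- sapply(c(2, 4, 6), function(gen) {
    cfg <- sim_config(n_lines = 60, generations = gen, seed = 13)
    mean(truth_het_fraction(simulate_ril_population(key, cfg))$het_frac)
  })
  expect_equal(hets, 2^-(c(2, 4, 6) - 1), tolerance = 0.35)
  expect_true(all(diff(hets) < 0))
})

test_that("skim call missingness matches the Poisson zero class", {
  d <- sim_dataset(n_lines = 50, n_chrom = 1, len = 20e6, density = 1 / 1e4,
                   coverage = 0.03, seed = 17)
  n_cells <- 50 * nrow(d$key)
  miss <- 1 - nrow(d$calls) / n_cells
  p0 <- exp(-0.03)
  se <- sqrt(p0 * (1 - p0) / n_cells)
  expect_lt(abs(miss - p0), 3 * se)
})

test_that("error-free high-coverage calls reproduce the truth", {
  g <- tiny_genome(len = 5e6, density = 1 / 2e4)
  key <- simulate_parents(g, seed = 19)
  cfg <- sim_config(n_lines = 8, coverage = 30, error = 0, seed = 19)
  truth <- simulate_ril_population(key, cfg)
  calls <- simulate_skim_calls(truth, key, cfg)
  # every site typed
  expect_equal(nrow(calls), 8 * nrow(key))
  hom <- truth$blocks[label != "H"]
  for (r in seq_len(nrow(hom))) {
    cl <- calls[line == hom$line[r] & chrom == hom$chrom[r] &
                  pos > hom$start[r] & pos <= hom$end[r]]
    expect_true(all(cl$code == hom$label[r]))
  }
})

test_that("identical seeds reproduce identical call tables", {
  d1 <- sim_dataset(n_lines = 5, seed = 31)
  d2 <- sim_dataset(n_lines = 5, seed = 31)
  expect_identical(as.data.frame(d1$calls), as.data.frame(d2$calls))
})

test_that("forbidden error rates are rejected", {
  expect_error(sim_config(error = 0.5), "error")
  expect_error(sim_config(coverage = 0), "coverage")
  expect_error(sim_config(desert_frac = 1), "desert_frac")
})

test_that("phenotypes follow the additive + epistasis + year model", {
  g <- tiny_genome(len = 20e6, density = 1 / 5e4)
  key <- simulate_parents(g, seed = 23)
  cfg <- sim_config(n_lines = 200, seed = 23)
  truth <- simulate_ril_population(key, cfg)
  # all effects zero: variance ~ sigma^2
  qs0 <- qtl_spec(loci = data.frame(chrom = "chr1", pos = 1e6, effect = 0),
                  sigma = 1)
  ph0 <- simulate_phenotypes(truth, qs0, seed = 1)
  expect_equal(var(ph0[year == 2021, value]), 1, tolerance = 0.3)
  # single locus, no noise: homozygous lines take two values 2a apart
  qs1 <- qtl_spec(loci = data.frame(chrom = "chr1", pos = 1e6, effect = 1),
                  sigma = 0)
  ph1 <- simulate_phenotypes(truth, qs1, seed = 1)
  x <- truth_genotypes(truth, data.frame(chrom = "chr1", pos = 1e6))
  hom_lines <- rownames(x)[x[, 1] != 0]
  vals <- sort(unique(ph1[line %in% hom_lines & year == 2021, value]))
  expect_equal(vals, c(-1, 1))
  # year effects shift means
  qs2 <- qtl_spec(loci = data.frame(chrom = "chr1", pos = 1e6, effect = 0),
                  sigma = 0.01, year_effects = c(0, 5))
  ph2 <- simulate_phenotypes(truth, qs2, seed = 2)
  expect_equal(mean(ph2[year == 2022, value]) -
                 mean(ph2[year == 2021, value]), 5, tolerance = 0.1)
})

test_that("realized PVE tracks the nominal analytic value", {
  # analytic oracle: a balanced +/-1 locus with effect a explains
  # a^2 / (a^2 + sigma^2); nominal 0.2 should be realized within 0.05
  g <- tiny_genome(len = 20e6, density = 1 / 5e4)
  key <- simulate_parents(g, seed = 29)
  a <- effect_for_pve(0.2)
  pves <- sapply(1:6, function(s) {
    cfg <- sim_config(n_lines = 300, seed = s)
    truth <- simulate_ril_population(key, cfg)
    qs <- qtl_spec(loci = data.frame(chrom = "chr1", pos = 10e6,
                                     effect = a),
                   sigma = 1, year_effects = c(0, 0))
    ph <- simulate_phenotypes(truth, qs, seed = s)
    attr(ph, "realized_pve")
  })
  # pooled phenotype averages two years of noise, so realized PVE on the
  # pooled scale is a^2 / (a^2 + sigma^2 / 2)
  nominal_pooled <- a^2 / (a^2 + 0.5)
  expect_lt(abs(mean(pves) - nominal_pooled), 0.05)
})

test_that("qualitative traits score 1/2/3 by thresholding", {
  g <- tiny_genome(len = 20e6, density = 1 / 5e4)
  key <- simulate_parents(g, seed = 37)
  cfg <- sim_config(n_lines = 100, seed = 37)
  truth <- simulate_ril_population(key, cfg)
  qs <- qtl_spec(loci = data.frame(chrom = "chr1", pos = 5e6, effect = 1),
                 sigma = 0, qualitative = TRUE, thresholds = c(-0.5, 0.5))
  ph <- simulate_phenotypes(truth, qs, seed = 1)
  expect_true(all(ph$value %in% 1:3))
  x <- truth_genotypes(truth, data.frame(chrom = "chr1", pos = 5e6))
  p1_lines <- rownames(x)[x[, 1] == 1]
  expect_true(all(ph[line %in% p1_lines, value] == 3))
})

test_that("loci outside the genome are rejected", {
  d <- sim_dataset(n_lines = 5, seed = 41)
  qs <- qtl_spec(loci = data.frame(chrom = "chr1", pos = 999e6, effect = 1))
  expect_error(simulate_phenotypes(d$truth, qs, seed = 1), "outside")
})
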