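# Shared fixtures: everything is generated in code at test time.

tiny_genome <- function(n_chrom = 1L, len = 10e6, density = 1 / 1e4) {
  genome_spec(paste0("chr", seq_len(n_chrom)), rep(len, n_chrom), density)
}

# A hand-built parent key on one chromosome with sites every `by` bp.
toy_key <- function(n = 20L, by = 1e5, chrom = "chr1", len = n * by + by) {
  key <- data.table::data.table(
    chrom = chrom, pos = as.double(seq_len(n)) * by,
    ref = "A", alt = "G",
    p1 = "ref", p2 = "alt"
  )
  data.table::setkey(key, chrom, pos)
  g <- genome_spec(chrom, len, n / len)
  data.table::setattr(key, "genome", g)
  data.table::setattr(key, "class", c("parent_key", class(key)))
  key[]
}

# One line's coded calls from explicit codes at regular spacing.
toy_calls <- function(codes, by = 1e5, line = "L1", chrom = "chr1") {
  calls <- data.table::data.table(
    line = line, chrom = chrom,
    pos = as.double(seq_along(codes)) * by, code = codes
  )
  data.table::setkey(calls, line, chrom, pos)
  data.table::setattr(calls, "lines", unique(calls$line))
  data.table::setattr(calls, "class", c("coded_calls", class(calls)))
  calls[]
}

# Build a bin_genotypes object directly from a character matrix.
toy_bin_genotypes <- function(geno, bin_size = 1e6) {
  cfg <- bin_config(bin_size = bin_size)
  n_bins <- ncol(geno)
  bins <- make_bins(setNames(n_bins * bin_size, "chr1"), cfg)
  colnames(geno) <- bins$bin
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("L%03d", seq_len(nrow(geno)))
  }
  structure(list(geno = geno, counts = NULL, bins = bins, cfg = cfg),
            class = "bin_genotypes")
}

# Small end-to-end simulated dataset reused by several tests.
sim_dataset <- function(n_lines = 30, n_chrom = 2, len = 50e6,
                        density = 1 / 2e4, coverage = 1, map_length = 1,
                        seed = 7, ...) {
  g <- genome_spec(paste0("chr", seq_len(n_chrom)), rep(len, n_chrom),
                   density)
  cfg <- sim_config(n_lines = n_lines, coverage = coverage,
                    map_length = map_length, seed = seed, ...)
  key <- simulate_parents(g, seed = seed)
  truth <- simulate_ril_population(key, cfg)
  calls <- simulate_skim_calls(truth, key, cfg)
  list(genome = g, cfg = cfg, key = key, truth = truth, calls = calls)
}
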