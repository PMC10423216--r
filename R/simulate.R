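# Synthetic skim-seq RIL population simulator.
#
# The generator emulates a wild x domesticated diploid selfing cross:
# a biallelic segregating parental key placed by a Poisson process, explicit
# per-generation selfing with Poisson crossover counts, a central
# recombination desert with U-shaped (Beta-distributed) distal crossover
# placement on each arm, Poisson read sampling at nominal skim coverage with
# per-read error, and phenotypes from additive + digenic-epistatic QTL with
# year effects.

#' Describe a genome for simulation
#'
#' @param chroms character vector of chromosome names.
#' @param lengths chromosome lengths in base pairs (same length as `chroms`).
#' @param snp_density expected segregating sites per base pair (scalar).
#' @param centromeres centromere position per chromosome in bp; defaults to
#'   the chromosome midpoints.
#' @return an object of class `genome_spec`.
#' @examples
#' genome_spec("chr1", 1e7, 1 / 2e4)
#' @export
genome_spec <- function(chroms, lengths, snp_density, centromeres = NULL) {
  stopifnot(length(chroms) == length(lengths), !anyDuplicated(chroms))
  if (any(lengths <= 0)) stop("chromosome lengths must be > 0")
  assert_scalar_num(snp_density, "snp_density", 0, strict_lower = TRUE)
  centromeres <- centromeres %||% (lengths / 2)
  stopifnot(length(centromeres) == length(lengths))
  if (any(centromeres <= 0 | centromeres >= lengths)) {
    stop("centromere positions must lie strictly inside their chromosomes")
  }
  structure(
    list(
      chroms = as.character(chroms), lengths = as.double(lengths),
      snp_density = snp_density, centromeres = as.double(centromeres)
    ),
    class = "genome_spec"
  )
}

#' Built-in genome presets
#'
#' `"scaled"` is the desk-scale default used in tests: 7 chromosomes of
#' 100 Mb with one segregating site per 20 kb. `"einkorn"` approximates the
#' full-size target system: a 5.1 Gb genome over 7 chromosomes with ~16.6 M
#' segregating sites (about one per 306 bp); it is provided for completeness
#' and is too large for routine testing.
#'
#' @param name preset name, `"scaled"` or `"einkorn"`.
#' @return a [genome_spec()].
#' @export
genome_preset <- function(name = c("scaled", "einkorn")) {
  name <- match.arg(name)
  switch(name,
    scaled = genome_spec(
      paste0("chr", 1:7), rep(100e6, 7), 1 / 20e3
    ),
    einkorn = genome_spec(
      paste0("chr", 1:7, "A"), rep(5.1e9 / 7, 7), 16687336 / 5.1e9
    )
  )
}

#' Simulation configuration
#'
#' @param n_lines number of RILs to simulate.
#' @param generations number of selfing generations counted from the F1
#'   (so `generations = 6` yields F6 lines with ~3% residual
#'   heterozygosity). Must be >= 2.
#' @param map_length meiotic map length per chromosome in Morgans (scalar or
#'   one value per chromosome); the expected crossovers per gamete.
#' @param desert_frac proportion of each chromosome, centered on the
#'   centromere, with zero crossover density (default 0.5).
#' @param arm_shape Beta shape parameter (both shapes equal) for crossover
#'   placement within each arm; values < 1 give the U-shaped, telomere-biased
#'   placement seen in Triticeae (default 0.5).
#' @param coverage mean reads per site per line (default 0.03).
#' @param error per-read probability of reporting the wrong parental allele
#'   (default 0.002). Must be < 0.5.
#' @param obligate_xo force at least one crossover per meiosis per
#'   chromosome (default FALSE; the crossover-count distribution is Poisson).
#' @param seed master seed; all stage randomness derives from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_lines = 300, generations = 6, map_length = 1,
                       desert_frac = 0.5, arm_shape = 0.5,
                       coverage = 0.03, error = 0.002,
                       obligate_xo = FALSE, seed = 1L) {
  assert_scalar_num(n_lines, "n_lines", 1)
  assert_scalar_num(generations, "generations", 2)
  if (any(map_length < 0)) stop("map_length must be >= 0")
  assert_scalar_num(desert_frac, "desert_frac", 0, 1, strict_upper = TRUE)
  assert_scalar_num(arm_shape, "arm_shape", 0, strict_lower = TRUE)
  assert_scalar_num(coverage, "coverage", 0, strict_lower = TRUE)
  assert_scalar_num(error, "error", 0, 0.5, strict_upper = TRUE)
  stopifnot(is.logical(obligate_xo), length(obligate_xo) == 1L)
  structure(
    list(
      n_lines = as.integer(n_lines), generations = as.integer(generations),
      map_length = as.double(map_length), desert_frac = desert_frac,
      arm_shape = arm_shape, coverage = coverage, error = error,
      obligate_xo = obligate_xo, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate the segregating parental key
#'
#' Places biallelic sites along each chromosome by a Poisson process at the
#' genome's SNP density. Every site is homozygous-different between the two
#' parents; parent 1 (the "wild-like" parent, matching the reference
#' assembly) carries the reference allele at a configurable proportion of
#' sites, emulating the reference-allele asymmetry seen when a wild parent
#' is called against a wild reference.
#'
#' @param genome a [genome_spec()].
#' @param seed integer seed.
#' @param p1_ref_prop proportion of sites at which parent 1 carries the
#'   reference allele (default 0.875).
#' @return a `parent_key`: a `data.table` with columns `chrom`, `pos`
#'   (1-based), `ref`, `alt` (nucleotides), `p1`, `p2` (each `"ref"` or
#'   `"alt"`), sorted by chromosome then position, with the genome attached
#'   as attribute `genome`.
#' @export
simulate_parents <- function(genome, seed = 1L, p1_ref_prop = 0.875) {
  stopifnot(inherits(genome, "genome_spec"))
  assert_scalar_num(p1_ref_prop, "p1_ref_prop", 0, 1)
  expected <- sum(genome$lengths) * genome$snp_density
  if (expected < 10) {
    stop("degenerate genome: expected segregating sites < 10 (",
         format(expected), ")")
  }
  set.seed(derive_seed(seed, 1L))
  per_chrom <- lapply(seq_along(genome$chroms), function(i) {
    n <- rpois(1L, genome$lengths[i] * genome$snp_density)
    pos <- sort(unique(ceiling(runif(n) * genome$lengths[i])))
    data.table(chrom = genome$chroms[i], pos = as.double(pos))
  })
  key <- rbindlist(per_chrom)
  nt <- c("A", "C", "G", "T")
  key[, ref := sample(nt, .N, replace = TRUE)]
  key[, alt := vapply(ref, function(r) sample(setdiff(nt, r), 1L), "")]
  key[, p1 := ifelse(runif(.N) < p1_ref_prop, "ref", "alt")]
  key[, p2 := ifelse(p1 == "ref", "alt", "ref")]
  setkey(key, chrom, pos)
  setattr(key, "genome", genome)
  setattr(key, "class", c("parent_key", class(key)))
  key[]
}

# -- meiosis machinery --------------------------------------------------------
# A haplotype is a run-length structure: `brk` (sorted interior breakpoints in
# bp) and `lab` (parental label 1/2 per block, length length(brk) + 1).

#' @noRd
hap_const <- function(label) list(brk = numeric(0), lab = label)

#' @noRd
hap_at <- function(hap, x) hap$lab[findInterval(x, hap$brk) + 1L]

#' @noRd
simplify_hap <- function(brk, lab) {
  if (length(brk)) {
    change <- lab[-1L] != lab[-length(lab)]
    brk <- brk[change]
    lab <- c(lab[1L], lab[-1L][change])
  }
  list(brk = brk, lab = lab)
}

#' @noRd
sample_xo_positions <- function(n_xo, chrom_len, centromere, desert_frac,
                                arm_shape) {
  if (n_xo == 0L) return(numeric(0))
  half <- desert_frac * chrom_len / 2
  left <- c(0, max(centromere - half, 0))
  right <- c(min(centromere + half, chrom_len), chrom_len)
  len_l <- left[2] - left[1]
  len_r <- right[2] - right[1]
  use_left <- runif(n_xo) < len_l / (len_l + len_r)
  u <- rbeta(n_xo, arm_shape, arm_shape)
  ifelse(use_left, left[1] + u * len_l, right[1] + u * len_r)
}

#' One meiosis: recombine two haplotypes into a gamete
#' @noRd
meiosis <- function(h1, h2, chrom_len, map_length, centromere, desert_frac,
                    arm_shape, obligate_xo) {
  n_xo <- rpois(1L, map_length)
  if (obligate_xo && n_xo == 0L) n_xo <- 1L
  xo <- sort(sample_xo_positions(n_xo, chrom_len, centromere, desert_frac,
                                 arm_shape))
  start <- sample(1:2, 1L)
  if (n_xo == 0L) {
    return(if (start == 1L) h1 else h2)
  }
  brk <- sort(unique(c(h1$brk, h2$brk, xo)))
  mids <- (c(0, brk) + c(brk, chrom_len)) / 2
  src <- 1L + (start - 1L + findInterval(mids, xo)) %% 2L
  lab <- ifelse(src == 1L, hap_at(h1, mids), hap_at(h2, mids))
  simplify_hap(brk, lab)
}

#' @noRd
genotype_blocks <- function(h1, h2, chrom_len) {
  brk <- sort(unique(c(h1$brk, h2$brk)))
  mids <- (c(0, brk) + c(brk, chrom_len)) / 2
  a <- hap_at(h1, mids)
  b <- hap_at(h2, mids)
  lab <- ifelse(a == b, ifelse(a == 1L, "P1", "P2"), "H")
  g <- simplify_hap(brk, lab)
  data.table(
    start = c(0, g$brk), end = c(g$brk, chrom_len), label = g$lab
  )
}

#' Simulate a selfed RIL population with known truth
#'
#' Starting from the F1 (one haplotype from each parent), each line is
#' selfed for `generations - 1` rounds; each round draws two independent
#' meioses with Poisson(`map_length`) crossovers per gamete, placed on the
#' chromosome arms outside the central recombination desert with a
#' symmetric Beta(`arm_shape`, `arm_shape`) density per arm. Residual
#' heterozygosity therefore decays as (1/2)^(generations - 1).
#'
#' @param key a `parent_key` from [simulate_parents()] (supplies the genome).
#' @param cfg a [sim_config()].
#' @return a `truth_set`: list with `blocks` (data.table `line`, `chrom`,
#'   `start`, `end`, `label` in P1/P2/H; 0-based half-open bp, tiling each
#'   chromosome), `breakpoints` (data.table `line`, `chrom`, `pos`,
#'   `left_state`, `right_state`, `is_crossover` — TRUE for P1/P2 label
#'   changes, FALSE where an H block is involved), the `genome`, and `cfg`.
#' @export
simulate_ril_population <- function(key, cfg) {
  stopifnot(inherits(key, "parent_key"), inherits(cfg, "sim_config"))
  genome <- attr(key, "genome")
  set.seed(derive_seed(cfg$seed, 2L))
  map_len <- rep_len(cfg$map_length, length(genome$chroms))
  blocks <- vector("list", cfg$n_lines * length(genome$chroms))
  k <- 0L
  for (li in seq_len(cfg$n_lines)) {
    for (ci in seq_along(genome$chroms)) {
      h1 <- hap_const(1L)
      h2 <- hap_const(2L)
      for (g in seq_len(cfg$generations - 1L)) {
        n1 <- meiosis(h1, h2, genome$lengths[ci], map_len[ci],
                      genome$centromeres[ci], cfg$desert_frac,
                      cfg$arm_shape, cfg$obligate_xo)
        n2 <- meiosis(h1, h2, genome$lengths[ci], map_len[ci],
                      genome$centromeres[ci], cfg$desert_frac,
                      cfg$arm_shape, cfg$obligate_xo)
        h1 <- n1
        h2 <- n2
      }
      gb <- genotype_blocks(h1, h2, genome$lengths[ci])
      gb[, `:=`(line = sprintf("RIL%04d", li), chrom = genome$chroms[ci])]
      k <- k + 1L
      blocks[[k]] <- gb
    }
  }
  blocks <- rbindlist(blocks)
  setcolorder(blocks, c("line", "chrom", "start", "end", "label"))
  bp <- blocks[, {
    n <- .N
    if (n > 1L) {
      list(
        pos = end[-n],
        left_state = label[-n],
        right_state = label[-1L]
      )
    } else {
      list(pos = numeric(0), left_state = character(0),
           right_state = character(0))
    }
  }, by = .(line, chrom)]
  bp[, is_crossover := left_state %in% c("P1", "P2") &
       right_state %in% c("P1", "P2")]
  structure(
    list(blocks = blocks, breakpoints = bp, genome = genome, cfg = cfg),
    class = "truth_set"
  )
}

#' Residual heterozygosity per line in a truth set
#'
#' @param truth a `truth_set`.
#' @return data.table with `line` and `het_frac`, the fraction of the genome
#'   in heterozygous blocks.
#' @export
truth_het_fraction <- function(truth) {
  stopifnot(inherits(truth, "truth_set"))
  total <- sum(truth$genome$lengths)
  truth$blocks[, .(het_frac = sum((end - start) * (label == "H")) / total),
               by = line]
}

#' True parental-origin genotype of each line at given loci
#'
#' @param truth a `truth_set`.
#' @param loci data.frame with columns `chrom` and `pos` (bp).
#' @return a numeric matrix (lines x loci) coded P1 = +1, P2 = -1, H = 0.
#' @export
truth_genotypes <- function(truth, loci) {
  stopifnot(inherits(truth, "truth_set"))
  loci <- as.data.table(loci)
  lines <- unique(truth$blocks$line)
  out <- matrix(NA_real_, length(lines), nrow(loci),
                dimnames = list(lines, NULL))
  for (j in seq_len(nrow(loci))) {
    cj <- loci$chrom[j]
    pj <- loci$pos[j]
    if (!cj %in% truth$genome$chroms ||
        pj < 0 || pj > truth$genome$lengths[match(cj, truth$genome$chroms)]) {
      stop(sprintf("locus %s:%g lies outside the genome", cj, pj))
    }
    hit <- truth$blocks[chrom == cj & start <= pj & end > pj,
                        .(line, label)]
    out[hit$line, j] <- c(P1 = 1, P2 = -1, H = 0)[hit$label]
  }
  out
}
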