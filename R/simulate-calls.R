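# Skim-coverage read sampling and phenotype generation on a simulated
# truth set.

#' Sample skim-sequencing calls from a simulated population
#'
#' Per line and site, the read count is Poisson(`coverage`); a site is typed
#' only if at least one read lands on it, so the missing fraction is
#' exp(-coverage) in expectation (~97% at the default 0.03x). Each read
#' reports the underlying parental allele with probability `1 - error`;
#' reads at heterozygous blocks draw either parental allele with equal
#' probability. Sites whose reads all match one parent are coded P1 or P2;
#' mixed-allele sites are coded H.
#'
#' @param truth a `truth_set` from [simulate_ril_population()].
#' @param key the `parent_key` the truth set was built on.
#' @param cfg the [sim_config()] (uses `coverage`, `error`, `seed`).
#' @return a `coded_calls` table: `data.table(line, chrom, pos, code)` with
#'   one row per typed site (missing sites implicit), plus attributes
#'   `lines` (all simulated line ids) and `genome`.
#' @export
simulate_skim_calls <- function(truth, key, cfg) {
  stopifnot(inherits(truth, "truth_set"), inherits(key, "parent_key"),
            inherits(cfg, "sim_config"))
  genome <- attr(key, "genome")
  set.seed(derive_seed(cfg$seed, 3L))
  lam <- cfg$coverage
  p_typed <- 1 - exp(-lam)
  lines <- unique(truth$blocks$line)
  out <- vector("list", length(lines) * length(genome$chroms))
  k_out <- 0L
  for (ci in genome$chroms) {
    kpos <- key[chrom == ci, pos]
    n_sites <- length(kpos)
    for (li in lines) {
      blk <- truth$blocks[line == li & chrom == ci]
      n_typed <- rbinom(1L, n_sites, p_typed)
      k_out <- k_out + 1L
      if (n_typed == 0L) next
      idx <- sort(sample.int(n_sites, n_typed))
      p <- kpos[idx]
      reads <- qpois(runif(n_typed, exp(-lam), 1), lam)
      lab <- blk$label[findInterval(p - 0.5, blk$start)]
      code <- character(n_typed)
      het <- lab == "H"
      if (any(!het)) {
        r <- reads[!het]
        wrong <- rbinom(length(r), r, cfg$error)
        truec <- lab[!het]
        other <- ifelse(truec == "P1", "P2", "P1")
        code[!het] <- ifelse(wrong == 0L, truec,
                             ifelse(wrong == r, other, "H"))
      }
      if (any(het)) {
        r <- reads[het]
        n1 <- rbinom(length(r), r, 0.5)
        code[het] <- ifelse(n1 == r, "P1", ifelse(n1 == 0L, "P2", "H"))
      }
      out[[k_out]] <- data.table(line = li, chrom = ci, pos = p, code = code)
    }
  }
  calls <- rbindlist(out[!vapply(out, is.null, TRUE)])
  setkey(calls, line, chrom, pos)
  setattr(calls, "lines", lines)
  setattr(calls, "genome", genome)
  setattr(calls, "class", c("coded_calls", class(calls)))
  calls[]
}

#' Specify the genetic architecture of simulated traits
#'
#' @param loci data.frame with columns `chrom`, `pos` (bp) and `effect`
#'   (additive effect `a`: half the difference between the two homozygote
#'   means, in trait units).
#' @param epistasis optional data.frame with columns `chrom1`, `pos1`,
#'   `chrom2`, `pos2`, `effect` (additive-by-additive interaction
#'   coefficient on the product of the two +/-1 locus codes).
#' @param mu intercept (trait units).
#' @param sigma residual standard deviation (trait units, >= 0).
#' @param years environment labels (default 2021:2022).
#' @param year_effects additive effect per year (trait units; default 0).
#' @param trait trait name.
#' @param qualitative if TRUE the latent value is thresholded into ordinal
#'   scores 1/2/3 (as used for visually scored traits such as coleoptile
#'   color).
#' @param thresholds length-2 increasing cut points on the latent scale for
#'   qualitative scoring (latent < t1 -> 1, < t2 -> 2, else 3).
#' @return an object of class `qtl_spec`.
#' @export
qtl_spec <- function(loci, epistasis = NULL, mu = 0, sigma = 1,
                     years = c(2021L, 2022L), year_effects = NULL,
                     trait = "trait1", qualitative = FALSE,
                     thresholds = c(-0.5, 0.5)) {
  loci <- as.data.table(loci)
  stopifnot(all(c("chrom", "pos", "effect") %in% names(loci)))
  if (!is.null(epistasis)) {
    epistasis <- as.data.table(epistasis)
    stopifnot(all(c("chrom1", "pos1", "chrom2", "pos2", "effect") %in%
                    names(epistasis)))
  }
  assert_scalar_num(sigma, "sigma", 0)
  year_effects <- year_effects %||% rep(0, length(years))
  stopifnot(length(year_effects) == length(years))
  if (qualitative) stopifnot(length(thresholds) == 2L, diff(thresholds) > 0)
  structure(
    list(loci = loci, epistasis = epistasis, mu = mu, sigma = sigma,
         years = years, year_effects = year_effects, trait = trait,
         qualitative = qualitative, thresholds = thresholds),
    class = "qtl_spec"
  )
}

#' Additive effect size giving a target proportion of variance explained
#'
#' For a balanced 1:1 biallelic locus coded +/-1, a single additive effect
#' `a` explains `a^2 / (a^2 + sigma^2)` of the phenotypic variance; this
#' inverts that relation.
#'
#' @param pve target proportion of variance explained, in (0, 1).
#' @param sigma residual standard deviation.
#' @return the additive effect `a`.
#' @export
effect_for_pve <- function(pve, sigma = 1) {
  assert_scalar_num(pve, "pve", 0, 1, strict_lower = TRUE,
                    strict_upper = TRUE)
  sigma * sqrt(pve / (1 - pve))
}

#' Simulate phenotypes from a truth set and a QTL specification
#'
#' Generates `y = mu + sum(a_k x_k) + sum(aa_ij x_i x_j) + year effect +
#' N(0, sigma^2)` per line and year, with locus codes x in {-1, +1} and
#' heterozygous blocks contributing 0. Qualitative traits threshold the
#' latent value into scores 1/2/3.
#'
#' @param truth a `truth_set`.
#' @param qtl a [qtl_spec()].
#' @param seed integer seed.
#' @return `data.table(line, trait, year, value)`; attribute `realized_pve`
#'   holds the per-locus variance fraction realized in the pooled
#'   (year-averaged) phenotype.
#' @export
simulate_phenotypes <- function(truth, qtl, seed = 1L) {
  stopifnot(inherits(truth, "truth_set"), inherits(qtl, "qtl_spec"))
  set.seed(derive_seed(seed, 4L))
  X <- truth_genotypes(truth, qtl$loci)
  lines <- rownames(X)
  g <- drop(X %*% qtl$loci$effect)
  if (!is.null(qtl$epistasis) && nrow(qtl$epistasis)) {
    Xi <- truth_genotypes(truth, data.table(chrom = qtl$epistasis$chrom1,
                                            pos = qtl$epistasis$pos1))
    Xj <- truth_genotypes(truth, data.table(chrom = qtl$epistasis$chrom2,
                                            pos = qtl$epistasis$pos2))
    g <- g + drop((Xi * Xj) %*% qtl$epistasis$effect)
  }
  out <- vector("list", length(qtl$years))
  for (yi in seq_along(qtl$years)) {
    latent <- qtl$mu + g + qtl$year_effects[yi] +
      rnorm(length(g), 0, qtl$sigma)
    val <- if (qtl$qualitative) {
      1L + findInterval(latent, qtl$thresholds)
    } else latent
    out[[yi]] <- data.table(line = lines, trait = qtl$trait,
                            year = qtl$years[yi], value = val)
  }
  pheno <- rbindlist(out)
  pooled <- pheno[, .(value = mean(value)), by = line]
  vy <- var(pooled$value)
  pve <- if (is.na(vy) || vy == 0) {
    rep(NA_real_, nrow(qtl$loci))
  } else {
    vapply(seq_len(nrow(qtl$loci)),
           function(k) var(X[, k] * qtl$loci$effect[k]) / vy, 0)
  }
  setattr(pheno, "realized_pve", pve)
  pheno[]
}

#' Pool a phenotype table across years
#'
#' The per-line arithmetic mean over years, the convention used for
#' interval-mapping input.
#'
#' @param pheno long phenotype table (`line`, `trait`, `year`, `value`).
#' @param trait_name trait to pool (default: the only trait present).
#' @return named numeric vector of pooled values, names = line ids.
#' @export
pool_phenotype <- function(pheno, trait_name = NULL) {
  pheno <- as.data.table(pheno)
  trait_name <- trait_name %||% unique(pheno$trait)
  stopifnot(length(trait_name) == 1L)
  pooled <- pheno[trait == trait_name, .(value = mean(value)), by = line]
  setNames(pooled$value, pooled$line)
}
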