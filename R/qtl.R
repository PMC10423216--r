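# Simplified trait mapping: single-marker LOD scan on bin genotypes with
# permutation thresholds, digenic epistasis on candidate bins, and a
# per-site association scan with FDR control on imputed genotypes.

#' Trait-scan settings
#'
#' @param permutations number of phenotype permutations for the
#'   genome-wide threshold (default 1000; minimum 100).
#' @param alpha genome-wide type-I error for the permutation threshold
#'   (default 0.05).
#' @param major_pve PVE above which a QTL is classed as major
#'   (default 0.10).
#' @param h_handling treatment of heterozygous bin codes: `"exclude"`
#'   (default) or `"code-zero"`.
#' @param subsample_frac fraction of sites used in the site-level
#'   association scan (default 0.10).
#' @param fdr_level Benjamini-Hochberg q-value cutoff for the site scan
#'   (default 0.05).
#' @param min_lines minimum informative lines per marker (default 20).
#' @param seed seed for permutations and site subsampling.
#' @return an object of class `scan_config`.
#' @export
scan_config <- function(permutations = 1000, alpha = 0.05, major_pve = 0.10,
                        h_handling = c("exclude", "code-zero"),
                        subsample_frac = 0.10, fdr_level = 0.05,
                        min_lines = 20, seed = 1L) {
  assert_scalar_num(permutations, "permutations", 100)
  assert_scalar_num(alpha, "alpha", 0, 1, strict_lower = TRUE,
                    strict_upper = TRUE)
  assert_scalar_num(subsample_frac, "subsample_frac", 0, 1,
                    strict_lower = TRUE)
  structure(list(permutations = as.integer(permutations), alpha = alpha,
                 major_pve = major_pve, h_handling = match.arg(h_handling),
                 subsample_frac = subsample_frac, fdr_level = fdr_level,
                 min_lines = as.integer(min_lines), seed = as.integer(seed)),
            class = "scan_config")
}

# Numeric genotype coding of a character code matrix: P1 -> +1, P2 -> -1,
# H -> 0 or NA depending on cfg.
#' @noRd
code_numeric <- function(geno, h_handling = "exclude") {
  G <- matrix(NA_real_, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  G[geno == "P1"] <- 1
  G[geno == "P2"] <- -1
  G[geno == "H"] <- if (h_handling == "code-zero") 0 else NA_real_
  G
}

# Vectorized per-column simple regression of y on each column of G.
# Returns effect, LOD = (n/2) log10(RSS0/RSS1), PVE, F-test p-value, n.
#' @noRd
scan_core <- function(G, y, min_lines = 20L, lod_cap = 300) {
  M <- !is.na(G)
  G0 <- G
  G0[!M] <- 0
  nj <- colSums(M)
  Sx <- colSums(G0)
  Sxx <- colSums(G0^2)
  Sy <- drop(crossprod(M, y))
  Syy <- drop(crossprod(M, y^2))
  Sxy <- drop(crossprod(G0, y))
  Sxx_c <- Sxx - Sx^2 / nj
  Sxy_c <- Sxy - Sx * Sy / nj
  RSS0 <- Syy - Sy^2 / nj
  eps <- 1e-12
  beta <- ifelse(Sxx_c > eps, Sxy_c / Sxx_c, NA_real_)
  RSS1 <- RSS0 - ifelse(Sxx_c > eps, Sxy_c^2 / Sxx_c, 0)
  ok <- nj >= min_lines & Sxx_c > eps & RSS0 > eps
  lod <- rep(NA_real_, length(nj))
  pve <- rep(NA_real_, length(nj))
  pval <- rep(NA_real_, length(nj))
  exact <- ok & RSS1 <= eps * RSS0
  lod[ok] <- pmin((nj[ok] / 2) * log10(RSS0[ok] / pmax(RSS1[ok], eps)),
                  lod_cap)
  lod[exact] <- lod_cap
  pve[ok] <- 1 - RSS1[ok] / RSS0[ok]
  Fstat <- (RSS0 - RSS1) * (nj - 2) / pmax(RSS1, eps)
  pval[ok] <- pf(Fstat[ok], 1, nj[ok] - 2, lower.tail = FALSE)
  list(effect = beta, lod = lod, pve = pve, p = pval, n = nj)
}

#' @noRd
align_scan_input <- function(geno, y, min_lines) {
  stopifnot(!is.null(names(y)))
  lines <- intersect(rownames(geno), names(y)[!is.na(y)])
  if (length(lines) < min_lines) {
    stop("fewer than ", min_lines, " lines with phenotype and genotype")
  }
  y <- y[lines]
  if (var(y) == 0) stop("phenotype is constant")
  list(geno = geno[lines, , drop = FALSE], y = y)
}

#' Single-marker LOD scan over bin genotypes
#'
#' Per bin, least-squares fit of `y = mu + beta g` with g coded P1 -> +1,
#' P2 -> -1 (H per `h_handling`); `LOD = (n/2) log10(RSS0 / RSS1)` and
#' `PVE = 1 - RSS1 / RSS0`. A perfect fit caps the LOD at 300.
#'
#' @param bg a `bin_genotypes` object.
#' @param y named numeric phenotype vector (names = line ids), e.g. from
#'   [pool_phenotype()].
#' @param cfg a [scan_config()].
#' @return `data.table(bin, chrom, start, n, effect, LOD, PVE, major)`,
#'   bins in genome order.
#' @export
single_marker_scan <- function(bg, y, cfg = scan_config()) {
  stopifnot(inherits(bg, "bin_genotypes"))
  ali <- align_scan_input(bg$geno, y, cfg$min_lines)
  G <- code_numeric(ali$geno, cfg$h_handling)
  sc <- scan_core(G, ali$y, cfg$min_lines)
  out <- data.table(bin = colnames(G))
  out <- bg$bins[, .(bin, chrom, start)][out, on = "bin"]
  out[, `:=`(n = sc$n, effect = sc$effect, LOD = sc$lod, PVE = sc$pve)]
  out[, major := !is.na(PVE) & PVE > cfg$major_pve]
  out[]
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the phenotype across lines (seeded), records the genome-wide
#' maximum LOD of each permutation, and returns the empirical
#' `1 - alpha` quantile (the `ceiling((1 - alpha) * permutations)`-th
#' order statistic).
#'
#' @inheritParams single_marker_scan
#' @return list with `threshold` and `max_lods` (one per permutation).
#' @export
permutation_threshold <- function(bg, y, cfg = scan_config()) {
  stopifnot(inherits(bg, "bin_genotypes"))
  ali <- align_scan_input(bg$geno, y, cfg$min_lines)
  G <- code_numeric(ali$geno, cfg$h_handling)
  set.seed(derive_seed(cfg$seed, 6L))
  max_lods <- vapply(seq_len(cfg$permutations), function(i) {
    yp <- sample(ali$y)
    max(scan_core(G, yp, cfg$min_lines)$lod, na.rm = TRUE)
  }, 0)
  k <- ceiling((1 - cfg$alpha) * cfg$permutations)
  list(threshold = sort(max_lods)[k], max_lods = max_lods)
}

#' Digenic epistasis scan over candidate bins
#'
#' For every pair of candidate bins, compares the additive model
#' `y = mu + b1 g1 + b2 g2` with the full model including the
#' additive-by-additive interaction `gamma g1 g2`; reports the interaction
#' LOD and the sign of gamma. Near-collinear pairs (genotype correlation
#' above 0.98, e.g. adjacent bins) are skipped.
#'
#' @param bg a `bin_genotypes` object.
#' @param y named phenotype vector.
#' @param candidates character vector of candidate bin ids; default: the
#'   top 3 bins per chromosome by single-marker LOD.
#' @param cfg a [scan_config()].
#' @return `data.table(bin1, bin2, n, gamma, int_LOD, skipped)`.
#' @export
epistasis_scan <- function(bg, y, candidates = NULL, cfg = scan_config()) {
  stopifnot(inherits(bg, "bin_genotypes"))
  if (is.null(candidates)) {
    sm <- single_marker_scan(bg, y, cfg)
    candidates <- sm[!is.na(LOD)][order(-LOD), head(.SD, 3L),
                                  by = chrom]$bin
  }
  if (length(candidates) < 2L) stop("need >= 2 candidate bins")
  ali <- align_scan_input(bg$geno[, candidates, drop = FALSE], y,
                          cfg$min_lines)
  G <- code_numeric(ali$geno, cfg$h_handling)
  pairs <- utils::combn(candidates, 2L)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    b1 <- pairs[1L, k]
    b2 <- pairs[2L, k]
    g1 <- G[, b1]
    g2 <- G[, b2]
    ok <- !is.na(g1) & !is.na(g2)
    n <- sum(ok)
    row <- data.table(bin1 = b1, bin2 = b2, n = n, gamma = NA_real_,
                      int_LOD = NA_real_, skipped = FALSE)
    if (n < cfg$min_lines || sd(g1[ok]) == 0 || sd(g2[ok]) == 0 ||
        abs(stats::cor(g1[ok], g2[ok])) > 0.98) {
      row$skipped <- TRUE
    } else {
      yy <- ali$y[ok]
      Xa <- cbind(1, g1[ok], g2[ok])
      Xf <- cbind(Xa, g1[ok] * g2[ok])
      fa <- stats::lm.fit(Xa, yy)
      ff <- stats::lm.fit(Xf, yy)
      rss_a <- sum(fa$residuals^2)
      rss_f <- sum(ff$residuals^2)
      row$gamma <- ff$coefficients[4L]
      row$int_LOD <- if (rss_f <= 1e-12 * rss_a) 300 else
        min((n / 2) * log10(rss_a / rss_f), 300)
    }
    out[[k]] <- row
  }
  rbindlist(out)
}

#' Per-site association scan on imputed genotypes
#'
#' Draws a seeded uniform subsample of sites at `subsample_frac`, fits the
#' single-marker regression per site, and applies Benjamini-Hochberg FDR
#' control.
#'
#' @param calls an (imputed) `coded_calls` table.
#' @param y named phenotype vector.
#' @param cfg a [scan_config()].
#' @return `data.table(chrom, pos, n, effect, p, q, significant)` for the
#'   subsampled sites, ordered by position.
#' @export
site_association_scan <- function(calls, y, cfg = scan_config()) {
  assert_coded_calls(calls)
  calls <- as.data.table(calls)
  sites <- unique(calls[, .(chrom, pos)])
  setkey(sites, chrom, pos)
  set.seed(derive_seed(cfg$seed, 7L))
  n_take <- floor(nrow(sites) * cfg$subsample_frac)
  if (n_take < 100L) {
    stop("site subsample smaller than 100 sites (", n_take, ")")
  }
  take <- sites[sort(sample.int(nrow(sites), n_take))]
  sub <- calls[take, on = c("chrom", "pos"), nomatch = NULL]
  sub[, site := paste0(chrom, ":", format(pos, scientific = FALSE,
                                          trim = TRUE))]
  wide <- dcast(sub, line ~ site, value.var = "code")
  lines <- wide$line
  geno <- as.matrix(wide[, -1L])
  rownames(geno) <- lines
  site_ids <- paste0(take$chrom, ":", format(take$pos, scientific = FALSE,
                                             trim = TRUE))
  geno <- geno[, site_ids, drop = FALSE]
  ali <- align_scan_input(geno, y, cfg$min_lines)
  G <- code_numeric(ali$geno, cfg$h_handling)
  sc <- scan_core(G, ali$y, cfg$min_lines)
  out <- data.table(chrom = take$chrom, pos = take$pos, n = sc$n,
                    effect = sc$effect, p = sc$p)
  out[, q := p.adjust(p, method = "BH")]
  out[, significant := !is.na(q) & q <= cfg$fdr_level]
  out[]
}
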