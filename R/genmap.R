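# Marker filtering, recombination fractions and Kosambi map distances.

#' Genetic-map settings
#'
#' @param seg_p segregation-distortion p-value threshold; bin markers whose
#'   P1:P2 line counts deviate from 1:1 with p below this are removed
#'   (default 0.001).
#' @param max_missing maximum missing fraction per bin marker
#'   (default 0.20).
#' @param ril_correction apply the Haldane-Waddington selfed-RIL correction
#'   to observed recombination fractions before the Kosambi conversion
#'   (default TRUE).
#' @return an object of class `map_config`.
#' @export
map_config <- function(seg_p = 0.001, max_missing = 0.20,
                       ril_correction = TRUE) {
  assert_scalar_num(seg_p, "seg_p", 0, 1, strict_lower = TRUE,
                    strict_upper = TRUE)
  assert_scalar_num(max_missing, "max_missing", 0, 1)
  structure(list(seg_p = seg_p, max_missing = max_missing,
                 ril_correction = isTRUE(ril_correction)),
            class = "map_config")
}

#' Filter bin markers on segregation distortion and missingness
#'
#' Per bin, a chi-square goodness-of-fit test (1 df) of the P1:P2 line
#' counts against 1:1 (H and missing codes excluded); bins with
#' `p < seg_p`, missing fraction above `max_missing`, or no informative
#' line are removed.
#'
#' @param bg a `bin_genotypes` object from [bin_matrix()].
#' @param cfg a [map_config()].
#' @return list with `retained` (character vector of bin ids) and `log`
#'   (`data.table(bin, nP1, nP2, missing_frac, p_value, removed, reason)`).
#' @export
filter_markers <- function(bg, cfg = map_config()) {
  stopifnot(inherits(bg, "bin_genotypes"))
  g <- bg$geno
  if (!nrow(g)) stop("empty bin genotype matrix")
  nP1 <- colSums(g == "P1", na.rm = TRUE)
  nP2 <- colSums(g == "P2", na.rm = TRUE)
  n <- nP1 + nP2
  miss <- colMeans(is.na(g))
  chisq <- ifelse(n > 0, (nP1 - n / 2)^2 / (n / 2) +
                    (nP2 - n / 2)^2 / (n / 2), NA_real_)
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  log <- data.table(bin = colnames(g), nP1 = nP1, nP2 = nP2,
                    missing_frac = miss, p_value = p)
  log[, reason := ""]
  log[n == 0, reason := "uninformative"]
  log[n > 0 & p < cfg$seg_p, reason := "segregation_distortion"]
  log[missing_frac > cfg$max_missing,
      reason := fifelse(reason == "", "missingness", paste0(reason,
                                                            "+missingness"))]
  log[, removed := reason != ""]
  list(retained = log[removed == FALSE, bin], log = log[])
}

#' Observed recombination fraction between two bin columns
#'
#' `R` = differing / informative, over lines that are non-missing and
#' non-heterozygous at both bins; capped just below 0.5 so map conversions
#' stay finite.
#'
#' @param a,b character vectors of codes for the two bins (same lines).
#' @param cap cap applied to R (default 0.4999).
#' @return the observed fraction R, or NA if no line is informative.
#' @export
adjacent_recombination_fraction <- function(a, b, cap = 0.4999) {
  ok <- !is.na(a) & !is.na(b) & a != "H" & b != "H"
  if (!any(ok)) return(NA_real_)
  min(mean(a[ok] != b[ok]), cap)
}

#' Haldane-Waddington correction for selfed RILs
#'
#' In a selfed RIL population the observed fraction of recombinant lines
#' between two loci is `R = 2r / (1 + 2r)` for meiotic recombination
#' fraction `r`; this inverts that map expansion: `r = R / (2 (1 - R))`.
#'
#' @param R observed RIL recombination fraction(s), in `[0, 0.5)`.
#' @return meiotic recombination fraction(s) `r`.
#' @export
haldane_waddington <- function(R) {
  if (any(!is.na(R) & (R < 0 | R >= 0.5))) {
    stop("R must lie in [0, 0.5); cap it first")
  }
  R / (2 * (1 - R))
}

#' Kosambi map distance
#'
#' `d = 25 ln((1 + 2r) / (1 - 2r))` centiMorgans; approximately `100 r` for
#' small `r`.
#'
#' @param r meiotic recombination fraction(s), in `[0, 0.5)`.
#' @return distance(s) in centiMorgans.
#' @export
kosambi_cm <- function(r) {
  if (any(!is.na(r) & (r < 0 | r >= 0.5))) {
    stop("r must lie in [0, 0.5)")
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Build the genetic map from bin genotypes
#'
#' Filters markers ([filter_markers()]), walks the retained bins of each
#' chromosome in physical order, estimates the adjacent-pair observed
#' recombination fraction, optionally applies the Haldane-Waddington RIL
#' correction, and accumulates Kosambi distances.
#'
#' @param bg a `bin_genotypes` object.
#' @param cfg a [map_config()].
#' @return list with `map` (`data.table(chrom, bin, R, r, interval_cM,
#'   cumulative_cM)`), `totals` (per chromosome, corrected and uncorrected
#'   cM), `total_cM`, `total_uncorrected_cM`, and `filter` (the
#'   [filter_markers()] result).
#' @export
build_map <- function(bg, cfg = map_config()) {
  stopifnot(inherits(bg, "bin_genotypes"))
  flt <- filter_markers(bg, cfg)
  bins <- bg$bins[bin %in% flt$retained]
  setorder(bins, chrom, start)
  g <- bg$geno
  maps <- list()
  totals <- list()
  for (cn in unique(bins$chrom)) {
    bb <- bins[chrom == cn, bin]
    if (length(bb) < 2L) {
      warning(sprintf("chromosome %s has < 2 retained bins; zero-length map",
                      cn))
      totals[[cn]] <- data.table(chrom = cn, cM = 0, uncorrected_cM = 0)
      if (length(bb) == 1L) {
        maps[[cn]] <- data.table(chrom = cn, bin = bb, R = NA_real_,
                                 r = NA_real_, interval_cM = 0,
                                 cumulative_cM = 0)
      }
      next
    }
    R <- vapply(seq_len(length(bb) - 1L), function(i) {
      adjacent_recombination_fraction(g[, bb[i]], g[, bb[i + 1L]])
    }, 0)
    R[is.na(R)] <- 0
    r <- if (cfg$ril_correction) haldane_waddington(R) else R
    d <- kosambi_cm(r)
    d_unc <- kosambi_cm(pmin(R, 0.4999))
    maps[[cn]] <- data.table(
      chrom = cn, bin = bb, R = c(NA, R), r = c(NA, r),
      interval_cM = c(0, d), cumulative_cM = cumsum(c(0, d))
    )
    totals[[cn]] <- data.table(chrom = cn, cM = sum(d),
                               uncorrected_cM = sum(d_unc))
  }
  map <- rbindlist(maps)
  tot <- rbindlist(totals)
  list(map = map, totals = tot,
       total_cM = sum(tot$cM), total_uncorrected_cM = sum(tot$uncorrected_cM),
       filter = flt)
}
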