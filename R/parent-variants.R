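# Filtering high-depth parental variant calls into the segregating key.

#' Parental-variant filter settings
#'
#' Site-level depth filters applied to both parents: total read depth within
#' `[min_depth, max_depth]` and the called (supporting) allele backed by at
#' least `min_allele_depth` reads.
#'
#' @param min_depth minimum total read depth per parent (default 6).
#' @param max_depth maximum total read depth per parent (default 100).
#' @param min_allele_depth minimum read depth of each parent's called allele
#'   (default 3).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(min_depth = 6, max_depth = 100,
                          min_allele_depth = 3) {
  assert_scalar_num(min_depth, "min_depth", 1)
  assert_scalar_num(max_depth, "max_depth", min_depth)
  assert_scalar_num(min_allele_depth, "min_allele_depth", 1)
  structure(list(min_depth = min_depth, max_depth = max_depth,
                 min_allele_depth = min_allele_depth),
            class = "filter_config")
}

#' @noRd
normalize_gt <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep(NA_character_, length(gt))
  out[gt %in% "0/0"] <- "hom_ref"
  out[gt %in% "1/1"] <- "hom_alt"
  out[gt %in% c("0/1", "1/0")] <- "het"
  out
}

#' Filter parental variant records into the segregating key
#'
#' A site is retained only if, for both parents, the genotype call is
#' homozygous and non-missing, the total depth lies within the configured
#' range, and the depth of that parent's called allele meets the minimum;
#' and the two parents carry different alleles. Every retained site is then
#' fully informative: a single error-free progeny read identifies its
#' parental origin. Indel and multi-allelic records are dropped (counted in
#' the attached filter log).
#'
#' @param records data.frame of parental site records with columns `chrom`,
#'   `pos`, `ref`, `alt`, and per parent `p1_gt`, `p1_dp`, `p1_ad_ref`,
#'   `p1_ad_alt` (likewise `p2_*`). Genotypes are VCF-style strings
#'   (`"0/0"`, `"1/1"`, `"0/1"`, `"./."`).
#' @param cfg a [filter_config()].
#' @param genome optional [genome_spec()] to attach to the key.
#' @return a `parent_key` (`chrom`, `pos`, `ref`, `alt`, `p1`, `p2` with
#'   `p1`/`p2` in `"ref"`/`"alt"`), sorted by chromosome then position.
#'   Attribute `filter_log` tabulates exclusion reasons.
#' @export
filter_parent_sites <- function(records, cfg = filter_config(),
                                genome = NULL) {
  stopifnot(inherits(cfg, "filter_config"))
  rec <- as.data.table(records)
  need <- c("chrom", "pos", "ref", "alt",
            "p1_gt", "p1_dp", "p1_ad_ref", "p1_ad_alt",
            "p2_gt", "p2_dp", "p2_ad_ref", "p2_ad_alt")
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    stop("parental records lack columns: ", paste(miss, collapse = ", "))
  }
  for (col in c("p1_dp", "p1_ad_ref", "p1_ad_alt",
                "p2_dp", "p2_ad_ref", "p2_ad_alt")) {
    bad <- which(is.na(rec[[col]]))
    if (length(bad)) {
      stop(sprintf("missing depth field '%s' at site %s:%s", col,
                   rec$chrom[bad[1]], format(rec$pos[bad[1]])))
    }
  }
  dup <- duplicated(rec[, .(chrom, pos)])
  if (any(dup)) {
    stop(sprintf("duplicate coordinate %s:%s", rec$chrom[dup][1],
                 format(rec$pos[dup][1])))
  }

  log <- c(input = nrow(rec))
  snp <- nchar(rec$ref) == 1L & nchar(rec$alt) == 1L &
    rec$ref %in% c("A", "C", "G", "T") & rec$alt %in% c("A", "C", "G", "T")
  log["non_snp_or_multiallelic"] <- sum(!snp)
  rec <- rec[snp]

  g1 <- normalize_gt(rec$p1_gt)
  g2 <- normalize_gt(rec$p2_gt)
  hom <- g1 %in% c("hom_ref", "hom_alt") & g2 %in% c("hom_ref", "hom_alt")
  log["het_or_missing"] <- sum(!hom)
  depth_ok <- rec$p1_dp >= cfg$min_depth & rec$p1_dp <= cfg$max_depth &
    rec$p2_dp >= cfg$min_depth & rec$p2_dp <= cfg$max_depth
  sup1 <- ifelse(g1 == "hom_ref", rec$p1_ad_ref, rec$p1_ad_alt)
  sup2 <- ifelse(g2 == "hom_ref", rec$p2_ad_ref, rec$p2_ad_alt)
  sup_ok <- !is.na(sup1) & !is.na(sup2) &
    sup1 >= cfg$min_allele_depth & sup2 >= cfg$min_allele_depth
  log["depth"] <- sum(hom & !depth_ok)
  log["allele_depth"] <- sum(hom & depth_ok & !sup_ok)
  seg <- g1 != g2
  log["non_segregating"] <- sum(hom & depth_ok & sup_ok & !seg)

  keep_i <- hom & depth_ok & sup_ok & seg
  key <- rec[keep_i, .(chrom, pos = as.double(pos), ref, alt)]
  key[, p1 := ifelse(g1[keep_i] == "hom_ref", "ref", "alt")]
  key[, p2 := ifelse(p1 == "ref", "alt", "ref")]
  setkey(key, chrom, pos)
  log["retained"] <- nrow(key)
  setattr(key, "filter_log", log)
  if (!is.null(genome)) setattr(key, "genome", genome)
  setattr(key, "class", c("parent_key", class(key)))
  key[]
}

#' Proportion of key sites at which each parent carries the reference allele
#'
#' @param key a `parent_key`.
#' @return named numeric vector `c(p1_ref = ..., p2_ref = ...)`.
#' @export
parent_allele_proportions <- function(key) {
  stopifnot(inherits(key, "parent_key"))
  if (nrow(key) == 0L) stop("empty parent key")
  c(p1_ref = mean(key$p1 == "ref"), p2_ref = mean(key$p2 == "ref"))
}
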