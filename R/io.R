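# Plain-file interfaces: TSV interchange for every stage and VCF for the
# field-standard entry/exit points. VCF is written directly (fixed,
# well-defined columns) and read through VariantAnnotation.

#' Write / read the parent key as TSV
#'
#' Six columns: `chrom`, `pos` (1-based), `ref`, `alt`, `p1`, `p2`.
#' @param key a `parent_key`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_parent_key_tsv <- function(key, path) {
  stopifnot(inherits(key, "parent_key"))
  fwrite(as.data.table(key), path, sep = "\t")
  invisible(path)
}

#' @rdname write_parent_key_tsv
#' @param genome optional [genome_spec()] to attach.
#' @export
read_parent_key_tsv <- function(path, genome = NULL) {
  key <- fread(path, colClasses = list(double = "pos"))
  stopifnot(all(c("chrom", "pos", "ref", "alt", "p1", "p2") %in% names(key)))
  setkey(key, chrom, pos)
  if (!is.null(genome)) setattr(key, "genome", genome)
  setattr(key, "class", c("parent_key", class(key)))
  key[]
}

#' Write / read coded calls as long TSV
#'
#' Four columns: `line`, `chrom`, `pos`, `code`; untyped sites are
#' implicit.
#' @param calls a `coded_calls` table.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_coded_calls_tsv <- function(calls, path) {
  assert_coded_calls(calls)
  fwrite(as.data.table(calls), path, sep = "\t")
  invisible(path)
}

#' @rdname write_coded_calls_tsv
#' @param lines optional full vector of line ids (lines can be typed at
#'   zero sites and then absent from the file).
#' @param genome optional [genome_spec()] to attach.
#' @export
read_coded_calls_tsv <- function(path, lines = NULL, genome = NULL) {
  calls <- fread(path, colClasses = list(double = "pos"))
  assert_coded_calls(calls)
  setkey(calls, line, chrom, pos)
  setattr(calls, "lines", lines %||% unique(calls$line))
  if (!is.null(genome)) setattr(calls, "genome", genome)
  setattr(calls, "class", c("coded_calls", class(calls)))
  calls[]
}

#' @noRd
vcf_header <- function(samples, contigs = NULL) {
  c("##fileformat=VCFv4.2",
    "##source=skimbin",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%.0f>", names(contigs), contigs)
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

#' Write the parent key as a two-sample VCF
#'
#' Samples `P1` and `P2`, each homozygous for its key allele (GT and a
#' nominal AD consistent with the call).
#'
#' @param key a `parent_key`.
#' @param path output file (plain text).
#' @param depth nominal per-allele depth written to AD (default 30).
#' @return `path`, invisibly.
#' @export
write_parent_key_vcf <- function(key, path, depth = 30L) {
  stopifnot(inherits(key, "parent_key"))
  genome <- attr(key, "genome")
  contigs <- if (!is.null(genome)) setNames(genome$lengths, genome$chroms)
  gt1 <- ifelse(key$p1 == "ref", "0/0", "1/1")
  gt2 <- ifelse(key$p2 == "ref", "0/0", "1/1")
  ad <- function(gt) ifelse(gt == "0/0", sprintf("%d,0", depth),
                            sprintf("0,%d", depth))
  body <- paste(key$chrom, sprintf("%.0f", key$pos), ".", key$ref, key$alt,
                ".", "PASS", ".", "GT:AD",
                paste0(gt1, ":", ad(gt1)), paste0(gt2, ":", ad(gt2)),
                sep = "\t")
  writeLines(c(vcf_header(c("P1", "P2"), contigs), body), path)
  invisible(path)
}

#' Write coded progeny calls as a multi-sample VCF
#'
#' One sample per line; codes are translated back to genotypes on the
#' key's ref/alt alleles (P1/P2 to the corresponding homozygote, H to
#' 0/1). AD carries a minimal depth consistent with the call (1 read for a
#' homozygote, 1+1 for a heterozygote) since per-read depths are not
#' retained in the coded representation.
#'
#' @param calls a `coded_calls` table.
#' @param key the `parent_key`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_progeny_vcf <- function(calls, key, path) {
  assert_coded_calls(calls)
  stopifnot(inherits(key, "parent_key"))
  genome <- attr(key, "genome")
  contigs <- if (!is.null(genome)) setNames(genome$lengths, genome$chroms)
  lines <- attr(calls, "lines") %||% sort(unique(calls$line))
  calls <- as.data.table(calls)
  kk <- key[, .(chrom, pos, ref, alt, p1)]
  x <- kk[calls, on = c("chrom", "pos"), nomatch = NULL]
  x[, gt := fifelse(code == "H", "0/1",
                    fifelse((code == "P1") == (p1 == "ref"), "0/0", "1/1"))]
  x[, field := fifelse(gt == "0/0", paste0(gt, ":1,0"),
                       fifelse(gt == "1/1", paste0(gt, ":0,1"),
                               paste0(gt, ":1,1")))]
  wide <- dcast(x, chrom + pos + ref + alt ~ factor(line, levels = lines),
                value.var = "field", drop = FALSE)
  setkey(wide, chrom, pos)
  sample_cols <- as.matrix(wide[, -(1:4)])
  sample_cols[is.na(sample_cols)] <- "./.:0,0"
  body <- paste(wide$chrom, sprintf("%.0f", wide$pos), ".", wide$ref,
                wide$alt, ".", "PASS", ".", "GT:AD",
                apply(sample_cols, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(vcf_header(lines, contigs), body), path)
  invisible(path)
}

#' Read a two-parent VCF into parental site records
#'
#' Uses VariantAnnotation; expects GT, DP and AD genotype fields for the
#' two named parent samples. The result feeds [filter_parent_sites()].
#'
#' @param path VCF file.
#' @param p1,p2 sample names of the two parents.
#' @return data.table of parental site records.
#' @export
read_parent_vcf <- function(path, p1, p2) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- as.data.frame(SummarizedExperiment::rowRanges(vcf))
  gt <- VariantAnnotation::geno(vcf)$GT
  ad <- VariantAnnotation::geno(vcf)$AD
  dp <- if ("DP" %in% names(VariantAnnotation::geno(vcf))) {
    VariantAnnotation::geno(vcf)$DP
  } else NULL
  stopifnot(all(c(p1, p2) %in% colnames(gt)))
  alt <- vapply(rr$ALT, function(a) {
    if (length(a)) as.character(a)[1L] else NA_character_
  }, "")
  pick_ad <- function(sample, idx) {
    if (is.array(ad) && length(dim(ad)) == 3L) {
      return(as.integer(ad[, sample, idx]))
    }
    vapply(ad[, sample], function(v) {
      if (length(v) >= idx && !is.na(v[idx])) as.integer(v[idx]) else 0L
    }, 0L)
  }
  ad1r <- pick_ad(p1, 1L); ad1a <- pick_ad(p1, 2L)
  ad2r <- pick_ad(p2, 1L); ad2a <- pick_ad(p2, 2L)
  data.table(
    chrom = as.character(rr$seqnames),
    pos = as.double(rr$start),
    ref = as.character(rr$REF), alt = alt,
    p1_gt = gt[, p1], p1_dp = if (is.null(dp)) ad1r + ad1a else
      as.integer(dp[, p1]),
    p1_ad_ref = ad1r, p1_ad_alt = ad1a,
    p2_gt = gt[, p2], p2_dp = if (is.null(dp)) ad2r + ad2a else
      as.integer(dp[, p2]),
    p2_ad_ref = ad2r, p2_ad_alt = ad2a
  )
}

#' Read a multi-sample progeny VCF into long genotype calls
#'
#' @param path VCF file.
#' @return `data.table(line, chrom, pos, gt)` with one row per called
#'   (non-missing) genotype, ready for [assign_parental_codes()].
#' @export
read_progeny_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- as.data.frame(SummarizedExperiment::rowRanges(vcf))
  gt <- VariantAnnotation::geno(vcf)$GT
  out <- data.table(
    chrom = rep(as.character(rr$seqnames), ncol(gt)),
    pos = rep(as.double(rr$start), ncol(gt)),
    line = rep(colnames(gt), each = nrow(gt)),
    gt = as.vector(gt)
  )
  out[gt != "./." & gt != ".|." & gt != "."]
}

#' Write a bin genotype matrix as wide TSV
#'
#' Rows are lines, columns are bins (`chrom:start-end`, 0-based half-open
#' coordinates); values use the legend A = P1, B = P2, H, NA.
#'
#' @param bg a `bin_genotypes` object.
#' @param path output file.
#' @param counts_path optional path for the per-cell count table.
#' @return `path`, invisibly.
#' @export
write_bin_matrix_tsv <- function(bg, path, counts_path = NULL) {
  stopifnot(inherits(bg, "bin_genotypes"))
  legend <- c(P1 = "A", P2 = "B", H = "H")
  m <- bg$geno
  m[] <- legend[m]
  dt <- data.table(line = rownames(m))
  dt <- cbind(dt, as.data.table(m))
  hdr <- paste0("# bin coordinates are 0-based half-open; ",
                "legend: A=P1, B=P2, H=heterozygous, NA=missing")
  writeLines(hdr, path)
  fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  if (!is.null(counts_path)) fwrite(bg$counts, counts_path, sep = "\t")
  invisible(path)
}

#' Write / read a long phenotype table
#'
#' Columns `line`, `trait`, `year`, `value`.
#' @param pheno phenotype data.frame.
#' @param path file path.
#' @return `path` (write) or a data.table (read).
#' @export
write_phenotype_tsv <- function(pheno, path) {
  stopifnot(all(c("line", "trait", "year", "value") %in% names(pheno)))
  fwrite(as.data.table(pheno), path, sep = "\t")
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  pheno <- fread(path)
  stopifnot(all(c("line", "trait", "year", "value") %in% names(pheno)))
  pheno[]
}
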