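# 1-Mb bin consensus genotyping.

#' Bin-consensus settings
#'
#' @param threshold proportion of parental (P1/P2) site codes required to
#'   call a bin for one parent (default 0.7; must exceed 0.5).
#' @param min_sites minimum informative (P1 + P2) sites per bin before a
#'   consensus is called; sparser bins are NA (default 5).
#' @param bin_size bin width in bp (default 1,000,000).
#' @return an object of class `bin_config`.
#' @export
bin_config <- function(threshold = 0.7, min_sites = 5, bin_size = 1e6) {
  assert_scalar_num(threshold, "threshold", 0.5, 1, strict_lower = TRUE)
  assert_scalar_num(min_sites, "min_sites", 1)
  assert_scalar_num(bin_size, "bin_size", 1)
  structure(list(threshold = threshold, min_sites = as.integer(min_sites),
                 bin_size = as.double(bin_size)),
            class = "bin_config")
}

#' Tile chromosomes into fixed-width bins
#'
#' Bins are half-open `[start, start + bin_size)` with 0-based starts; the
#' final partial bin is included, so each chromosome contributes
#' `ceiling(length / bin_size)` bins.
#'
#' @param lengths named numeric vector of chromosome lengths (bp), or a
#'   [genome_spec()].
#' @param cfg a [bin_config()].
#' @return `data.table(chrom, bin, start, end)` with `bin` the global bin
#'   id `"chrom:start-end"`.
#' @export
make_bins <- function(lengths, cfg = bin_config()) {
  if (inherits(lengths, "genome_spec")) {
    lengths <- setNames(lengths$lengths, lengths$chroms)
  }
  if (is.null(names(lengths)) || any(!nzchar(names(lengths)))) {
    stop("chromosome lengths must be named")
  }
  if (any(lengths <= 0)) stop("chromosome lengths must be > 0")
  out <- lapply(names(lengths), function(cn) {
    len <- lengths[[cn]]
    starts <- seq(0, by = cfg$bin_size,
                  length.out = ceiling(len / cfg$bin_size))
    data.table(chrom = cn, start = starts,
               end = pmin(starts + cfg$bin_size, len))
  })
  idx <- rbindlist(out)
  idx[, bin := sprintf("%s:%.0f-%.0f", chrom, start, end)]
  setcolorder(idx, c("chrom", "bin", "start", "end"))
  setkey(idx, chrom, start)
  idx[]
}

#' Consensus genotype call for one bin
#'
#' With `n = nP1 + nP2` informative sites: NA when `n < min_sites`;
#' otherwise P1 when `nP1 / n >= threshold`, P2 when
#' `nP2 / n >= threshold`, else H. Vectorized over bins.
#'
#' @param nP1,nP2 counts of P1- and P2-coded sites in the bin.
#' @param cfg a [bin_config()].
#' @return character vector of consensus codes (`"P1"`, `"P2"`, `"H"`, NA).
#' @export
call_bin_consensus <- function(nP1, nP2, cfg = bin_config()) {
  stopifnot(length(nP1) == length(nP2), all(nP1 >= 0), all(nP2 >= 0))
  n <- nP1 + nP2
  p <- ifelse(n > 0, nP1 / n, NA_real_)
  out <- rep(NA_character_, length(n))
  ok <- n >= cfg$min_sites
  out[ok & p >= cfg$threshold] <- "P1"
  out[ok & (1 - p) >= cfg$threshold] <- "P2"
  out[ok & is.na(out)] <- "H"
  out
}

#' Aggregate site codes into the bin consensus genotype matrix
#'
#' Counts P1/P2/H site codes per (line, bin) and applies
#' [call_bin_consensus()]. H site codes do not enter the parental
#' proportion, but a bin dominated by H sites (`nH > nP1 + nP2`, with at
#' least `min_sites` codes in total) is called H outright rather than being
#' forced to a parent.
#'
#' @param calls a `coded_calls` table.
#' @param bins a bin index from [make_bins()].
#' @param cfg a [bin_config()].
#' @return a `bin_genotypes` list: `geno` (character matrix lines x bins,
#'   values P1/P2/H/NA, columns in genome order), `counts`
#'   (`data.table(line, bin, nP1, nP2, nH)` for non-empty cells), `bins`
#'   (the bin index), `cfg`.
#' @export
bin_matrix <- function(calls, bins, cfg = bin_config()) {
  assert_coded_calls(calls)
  calls <- as.data.table(calls)
  lines <- attr(calls, "lines") %||% sort(unique(calls$line))
  chroms <- unique(bins$chrom)
  if (length(bad <- setdiff(unique(calls$chrom), chroms))) {
    stop("site chromosome(s) outside the bin index: ",
         paste(bad, collapse = ", "))
  }
  chrom_len <- bins[, .(len = max(end)), by = chrom]
  x <- chrom_len[calls, on = "chrom"]
  if (x[, any(pos < 1 | pos > len)]) {
    stop("site position outside its chromosome")
  }
  x[, start := (ceiling(pos) - 1) %/% cfg$bin_size * cfg$bin_size]
  x <- bins[, .(chrom, start, bin)][x, on = c("chrom", "start")]
  counts <- x[, .(nP1 = sum(code == "P1"), nP2 = sum(code == "P2"),
                  nH = sum(code == "H")), by = .(line, bin)]
  counts[, consensus := call_bin_consensus(nP1, nP2, cfg)]
  counts[nH > nP1 + nP2 & nP1 + nP2 + nH >= cfg$min_sites, consensus := "H"]
  geno <- matrix(NA_character_, length(lines), nrow(bins),
                 dimnames = list(lines, bins$bin))
  geno[cbind(match(counts$line, lines), match(counts$bin, bins$bin))] <-
    counts$consensus
  structure(
    list(geno = geno, counts = counts[, .(line, bin, nP1, nP2, nH)],
         bins = copy(bins), cfg = cfg),
    class = "bin_genotypes"
  )
}
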