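# Coding low-coverage progeny calls by parental origin and screening lines.

#' Assign parental-origin codes to progeny variant calls
#'
#' Each progeny genotype call at a key site is matched to the parental
#' alleles: a homozygous call equal to parent 1's allele becomes `P1`, equal
#' to parent 2's allele becomes `P2`, a heterozygous call becomes `H`.
#' Calls at coordinates absent from the key, missing calls, and calls
#' referencing an allele carried by neither parent (third-allele noise,
#' counted and reported with a warning) are dropped.
#'
#' @param progeny data.frame of progeny calls with columns `line`, `chrom`,
#'   `pos`, `gt` (VCF-style genotype string on the same reference as the
#'   key).
#' @param key a `parent_key`.
#' @return a `coded_calls` table (`line`, `chrom`, `pos`, `code`), keyed by
#'   line/chrom/pos, with attributes `lines` and (if present on the key)
#'   `genome`.
#' @export
assign_parental_codes <- function(progeny, key) {
  stopifnot(inherits(key, "parent_key"))
  prog <- as.data.table(progeny)
  need <- c("line", "chrom", "pos", "gt")
  miss <- setdiff(need, names(prog))
  if (length(miss)) {
    stop("progeny call table lacks columns: ", paste(miss, collapse = ", "))
  }
  all_lines <- unique(prog$line)
  prog <- prog[!is.na(gt)]
  gt <- gsub("|", "/", prog$gt, fixed = TRUE)
  cls <- rep(NA_character_, length(gt))
  cls[gt == "0/0"] <- "ref"
  cls[gt == "1/1"] <- "alt"
  cls[gt %in% c("0/1", "1/0")] <- "het"
  third <- !is.na(gt) & gt != "./." & is.na(cls)
  if (any(third)) {
    warning(sum(third), " progeny calls matched neither parental allele ",
            "and were dropped")
  }
  prog <- prog[!is.na(cls)]
  cls <- cls[!is.na(cls)]
  prog[, pos := as.double(pos)]
  prog[, gt_class := cls]
  hit <- key[, .(chrom, pos, p1)][prog, on = c("chrom", "pos"),
                                  nomatch = NULL]
  hit[, code := ifelse(gt_class == "het", "H",
                       ifelse(gt_class == p1, "P1", "P2"))]
  calls <- hit[, .(line, chrom, pos, code)]
  setkey(calls, line, chrom, pos)
  setattr(calls, "lines", all_lines)
  if (!is.null(attr(key, "genome"))) {
    setattr(calls, "genome", attr(key, "genome"))
  }
  setattr(calls, "class", c("coded_calls", class(calls)))
  calls[]
}

#' Screen out excessively heterozygous lines
#'
#' In a selfed RIL population residual heterozygosity should be low (~3% at
#' F6); lines whose fraction of H codes among typed sites strictly exceeds
#' `max_h_frac` are flagged as removed (they are typically outcrossed or
#' contaminated). Lines at exactly the threshold are retained. Lines with
#' zero typed sites are removed with reason `"untyped"`.
#'
#' @param calls a `coded_calls` table.
#' @param max_h_frac maximum tolerated H fraction among typed sites
#'   (default 0.10).
#' @return list with `qc` (`data.table(line, n_typed, frac_H, retained,
#'   reason)`) and `calls` (the input restricted to retained lines, same
#'   attributes).
#' @export
screen_heterozygous_lines <- function(calls, max_h_frac = 0.10) {
  assert_coded_calls(calls)
  assert_scalar_num(max_h_frac, "max_h_frac", 0, 1)
  calls <- as.data.table(calls)
  lines <- attr(calls, "lines") %||% unique(calls$line)
  qc <- calls[, .(n_typed = .N, frac_H = mean(code == "H")), by = line]
  qc <- qc[data.table(line = lines), on = "line"]
  qc[is.na(n_typed), `:=`(n_typed = 0L, frac_H = NA_real_)]
  qc[, retained := n_typed > 0L & frac_H <= max_h_frac]
  qc[, reason := fifelse(n_typed == 0L, "untyped",
                         fifelse(retained, "", "excess_heterozygosity"))]
  kept <- calls[line %in% qc[retained == TRUE, line]]
  setkey(kept, line, chrom, pos)
  setattr(kept, "lines", qc[retained == TRUE, line])
  if (!is.null(attr(calls, "genome"))) {
    setattr(kept, "genome", attr(calls, "genome"))
  }
  setattr(kept, "class", c("coded_calls", class(kept)))
  list(qc = qc[], calls = kept[])
}
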