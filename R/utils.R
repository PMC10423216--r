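#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' All stochastic stages draw their randomness from one master seed; stage
#' seeds are derived deterministically so that stages can be re-run in
#' isolation with identical results. Results stay below 2^31 - 1.
#'
#' @param seed master seed (single non-negative integer).
#' @param stream integer stream index (>= 1) identifying the consumer.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  # 64-bit-safe affine mix done in double precision; exact below 2^53
  x <- (as.double(seed) * 2654435761 + as.double(stream) * 40503 + 12345)
  as.integer(x %% 2147483629)
}

#' Parental-origin genotype codes
#'
#' Codes used throughout: `"P1"` (allele of parent 1), `"P2"` (allele of
#' parent 2), `"H"` (heterozygous). Missing is `NA`.
#' @keywords internal
#' @noRd
CODES <- c("P1", "P2", "H")

#' @noRd
assert_codes <- function(x) {
  bad <- !is.na(x) & !(x %in% CODES)
  if (any(bad)) {
    stop("invalid genotype codes: ", paste(unique(x[bad]), collapse = ", "))
  }
  invisible(TRUE)
}

#' @noRd
assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf(
      "'%s' must be in %s%s, %s%s (got %g)", name,
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]", x
    ))
  }
  invisible(TRUE)
}

#' Validate a long-format coded call table
#'
#' The sparse call matrix is stored long: one row per typed (line, site)
#' with columns `line`, `chrom`, `pos`, `code`; untyped sites are implicit.
#' @noRd
assert_coded_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  need <- c("line", "chrom", "pos", "code")
  miss <- setdiff(need, names(calls))
  if (length(miss)) {
    stop("coded call table lacks columns: ", paste(miss, collapse = ", "))
  }
  assert_codes(calls$code)
  invisible(TRUE)
}
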