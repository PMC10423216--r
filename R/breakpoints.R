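# Crossover-breakpoint detection from sparse parental-origin site codes.
#
# A paired 6.5-Mb sliding window ("roaming score") contrasts the parental
# composition on either side of each candidate position; a recursive
# filtering pass keeps the highest-scoring, mutually consistent breakpoints
# and a second pass re-scans with windows narrowed to the surrounding
# accepted breakpoints so that nearby (double) crossovers are recovered.
# The score is a two-proportion contrast |p_left - p_right| *
# sqrt(n_L n_R / (n_L + n_R)) / sqrt(n_min): zero for identical window
# composition and growing with both the contrast and the supporting counts.

#' Breakpoint-detection settings
#'
#' @param window paired sliding-window width in bp (default 6,500,000).
#' @param min_sites minimum informative (P1/P2) sites per window before it
#'   is classified (default 10).
#' @param purity minimum P1 (or P2) proportion for a window to be called
#'   parental (default 0.9).
#' @param h_band proportion interval classified heterozygous, symmetric
#'   about 0.5 (default `c(0.4, 0.6)`).
#' @param min_score minimum accepted roaming score (default 0.5).
#' @param exclusion exclusion radius around an accepted breakpoint within
#'   which remaining candidates are suppressed in the first pass (default:
#'   the window width).
#' @return an object of class `breakpoint_config`.
#' @export
breakpoint_config <- function(window = 6.5e6, min_sites = 10, purity = 0.9,
                              h_band = c(0.4, 0.6), min_score = 0.5,
                              exclusion = NULL) {
  assert_scalar_num(window, "window", 0, strict_lower = TRUE)
  assert_scalar_num(min_sites, "min_sites", 1)
  assert_scalar_num(purity, "purity", 0.5, 1, strict_lower = TRUE)
  stopifnot(length(h_band) == 2L, h_band[1] <= h_band[2])
  if (abs((h_band[1] + h_band[2]) / 2 - 0.5) > 1e-9) {
    stop("h_band must be symmetric about 0.5")
  }
  assert_scalar_num(min_score, "min_score", 0)
  exclusion <- exclusion %||% window
  structure(list(window = window, min_sites = as.integer(min_sites),
                 purity = purity, h_band = h_band, min_score = min_score,
                 exclusion = exclusion),
            class = "breakpoint_config")
}

# Classification of a window: NA when too few parental sites or the
# composition is intermediate; H when the parental codes are near 1:1 or
# when observed-H codes dominate the window (direct evidence of a
# heterozygous block at multi-read coverage).
#' @noRd
classify_window <- function(n1, n2, cfg, min_sites = cfg$min_sites,
                            nH = 0) {
  n <- n1 + n2
  out <- rep(NA_character_, length(n))
  ok <- n >= min_sites
  # count-based comparisons (with an epsilon for exact boundaries) so the
  # rule is exactly P1/P2-symmetric
  eps <- 1e-9
  out[ok & n1 >= cfg$purity * n - eps] <- "P1"
  out[ok & n2 >= cfg$purity * n - eps] <- "P2"
  out[ok & n1 >= cfg$h_band[1] * n - eps &
        n2 >= cfg$h_band[1] * n - eps] <- "H"
  # H-code dominance: in homozygous windows observed-H codes are rare
  # (two reads hitting one site AND disagreeing), in heterozygous blocks
  # they are the majority once sites carry >1 read
  out[(n + nH >= min_sites) & nH >= 3 & nH > 0.5 * n] <- "H"
  out
}

# Cumulative site counts for one line/chromosome; pp are the positions of
# P1/P2-coded sites, ap all typed positions (for the H-code count).
#' @noRd
par_cums <- function(pos, code) {
  par <- code != "H"
  pp <- pos[par]
  list(pp = pp, c1 = cumsum(code[par] == "P1"),
       c2 = cumsum(code[par] == "P2"),
       ap = pos, cH = cumsum(code == "H"))
}

# Counts over (a, b] given cumulative structure.
#' @noRd
win_counts <- function(cc, a, b) {
  ia <- findInterval(a, cc$pp)
  ib <- findInterval(b, cc$pp)
  c1 <- c(0, cc$c1)
  c2 <- c(0, cc$c2)
  cH <- c(0, cc$cH)
  list(n1 = c1[ib + 1L] - c1[ia + 1L], n2 = c2[ib + 1L] - c2[ia + 1L],
       nH = cH[findInterval(b, cc$ap) + 1L] -
         cH[findInterval(a, cc$ap) + 1L])
}

#' Classify one side of a candidate position
#'
#' Counts P1/P2 site codes in the window `(x - window, x]` (side `"left"`)
#' or `(x, x + window]` (side `"right"`) and classifies the window as P1,
#' P2, H (near 1:1 composition) or NA (too few sites or intermediate
#' composition).
#'
#' @param codes data.frame with `pos` and `code` for one line on one
#'   chromosome, sorted by position.
#' @param x candidate position (bp).
#' @param side `"left"` or `"right"`.
#' @param cfg a [breakpoint_config()].
#' @return list with `side`, `nP1`, `nP2`, `p` and `class`.
#' @export
window_profile <- function(codes, x, side = c("left", "right"),
                           cfg = breakpoint_config()) {
  side <- match.arg(side)
  assert_codes(codes$code)
  cc <- par_cums(codes$pos, codes$code)
  w <- if (side == "left") win_counts(cc, x - cfg$window, x) else
    win_counts(cc, x, x + cfg$window)
  n <- w$n1 + w$n2
  list(side = side, nP1 = w$n1, nP2 = w$n2,
       p = if (n > 0) w$n1 / n else NA_real_,
       class = classify_window(w$n1, w$n2, cfg, nH = w$nH))
}

#' Score candidate crossover positions on one chromosome of one line
#'
#' Candidates are the midpoints between consecutive typed sites of
#' differing code (the score is piecewise constant between typed sites, so
#' no other positions need evaluation). Each candidate is scored by the
#' paired-window contrast; candidates where either window cannot be
#' classified score 0.
#'
#' @param codes data.frame with `pos` and `code` for one line on one
#'   chromosome, sorted by position.
#' @param cfg a [breakpoint_config()].
#' @return `data.table(x, score, nL, nR, pL, pR, classL, classR)`, one row
#'   per candidate, ordered by position.
#' @export
roaming_scan <- function(codes, cfg = breakpoint_config()) {
  assert_codes(codes$code)
  pos <- as.double(codes$pos)
  code <- as.character(codes$code)
  stopifnot(!is.unsorted(pos))
  n <- length(pos)
  empty <- data.table(x = numeric(0), score = numeric(0), nL = integer(0),
                      nR = integer(0), pL = numeric(0), pR = numeric(0),
                      classL = character(0), classR = character(0))
  if (n < 2L) return(empty)
  diff_adj <- code[-1L] != code[-n]
  if (!any(diff_adj)) return(empty)
  x <- (pos[-1L][diff_adj] + pos[-n][diff_adj]) / 2
  cc <- par_cums(pos, code)
  L <- win_counts(cc, x - cfg$window, x)
  R <- win_counts(cc, x, x + cfg$window)
  score_candidates(x, L, R, cfg)
}

#' @noRd
score_candidates <- function(x, L, R, cfg, min_sites = cfg$min_sites) {
  nL <- L$n1 + L$n2
  nR <- R$n1 + R$n2
  pL <- ifelse(nL > 0, L$n1 / nL, NA_real_)
  pR <- ifelse(nR > 0, R$n1 / nR, NA_real_)
  classL <- classify_window(L$n1, L$n2, cfg, min_sites, L$nH)
  classR <- classify_window(R$n1, R$n2, cfg, min_sites, R$nH)
  ok <- !is.na(classL) & !is.na(classR)
  s <- ifelse(ok,
              abs(pL - pR) * sqrt(nL * nR / pmax(nL + nR, 1)) /
                sqrt(cfg$min_sites),
              0)
  data.table(x = x, score = s, nL = nL, nR = nR, pL = pL, pR = pR,
             classL = classL, classR = classR)
}

# Re-evaluate a set of positions with windows truncated at the nearest
# accepted breakpoint (or the configured width, whichever is smaller).
#' @noRd
rescore_truncated <- function(x, left_lim, right_lim, cc, cfg,
                              min_sites, width = cfg$window) {
  wl <- pmin(width, x - left_lim)
  wr <- pmin(width, right_lim - x)
  L <- win_counts(cc, x - wl, x)
  R <- win_counts(cc, x, x + wr)
  score_candidates(x, L, R, cfg, min_sites)
}

# Multi-scale re-classification: per position, the largest width (halving
# from the configured one) at which both windows classify non-NA. A flank
# classified H is then re-examined at the smallest classifiable width: a
# window that straddles a further crossover looks 1:1 at full width but
# resolves to a pure parent up close, whereas a genuine heterozygous block
# stays near 1:1 at every scale.
#' @noRd
rescore_multiscale <- function(x, left_lim, right_lim, cc, cfg,
                               min_sites, widths) {
  best <- rescore_truncated(x, left_lim, right_lim, cc, cfg, min_sites,
                            widths[1L])
  for (wd in widths[-1L]) {
    need <- is.na(best$classL) | is.na(best$classR)
    if (!any(need)) break
    rs <- rescore_truncated(x[need], left_lim[need], right_lim[need],
                            cc, cfg, min_sites, wd)
    ok <- !is.na(rs$classL) & !is.na(rs$classR)
    if (any(ok)) {
      rows <- which(need)[ok]
      for (col in names(best)) {
        set(best, i = rows, j = col, value = rs[[col]][ok])
      }
    }
  }
  n_ref <- max(cfg$min_sites, min_sites)
  for (side in c("classL", "classR")) {
    for (i in which(best[[side]] %in% "H")) {
      cl2 <- refine_h_flank(cc, x[i], side == "classL", left_lim[i],
                            right_lim[i], n_ref, cfg)
      if (!is.na(cl2)) set(best, i = i, j = side, value = cl2)
    }
  }
  best
}

# A flank classified H (near 1:1) may in truth be a pure parental region
# seen through a window that straddles a further crossover. Decide from
# the two nearest disjoint blocks of n_ref parental sites: both must read
# the same pure parent (a genuine 1:1 heterozygous block passes this only
# with probability ~ (2 * 0.5^n_ref * n_ref)^2).
#' @noRd
refine_h_flank <- function(cc, x, left_side, left_lim, right_lim, n_ref,
                           cfg) {
  i_x <- findInterval(x, cc$pp)
  idx <- if (left_side) {
    lo <- findInterval(left_lim, cc$pp) + 1L
    if (i_x < lo) return(NA_character_)
    rev(seq(lo, i_x))          # nearest first
  } else {
    hi <- findInterval(right_lim, cc$pp)
    if (i_x + 1L > hi) return(NA_character_)
    seq(i_x + 1L, hi)
  }
  if (length(idx) < n_ref) return(NA_character_)
  is1 <- diff(c(0, cc$c1))[idx] == 1L
  b1 <- is1[seq_len(n_ref)]
  # observed-H codes across the span of the nearest block veto a
  # parental override: they are direct evidence of heterozygosity
  span <- range(cc$pp[idx[seq_len(n_ref)]])
  nH <- win_counts(cc, span[1L] - 1, span[2L])$nH
  if (nH >= 3 && nH > 0.5 * n_ref) return(NA_character_)
  n1 <- sum(b1)
  pure <- n1 %in% c(0L, n_ref)
  cl1 <- classify_window(n1, n_ref - n1, cfg, n_ref)
  if (is.na(cl1) || cl1 == "H") return(NA_character_)
  if (length(idx) >= 2L * n_ref) {
    b2 <- is1[(n_ref + 1L):(2L * n_ref)]
    cl2 <- classify_window(sum(b2), n_ref - sum(b2), cfg, n_ref)
    # agreement of the disjoint second block confirms; a heterozygous or
    # unclassifiable second block is tolerated only when the nearest
    # block is perfectly pure (true crossover flanked by a het block)
    if (identical(cl2, cl1)) return(cl1)
    if (!identical(cl2, "P1") && !identical(cl2, "P2") && pure) return(cl1)
    return(NA_character_)
  }
  # no second block available: require the first to be perfectly pure
  if (pure) cl1 else NA_character_
}

#' Resolve scored candidates into a breakpoint list
#'
#' Pass 1 repeatedly accepts the highest-scoring candidate whose two window
#' classes differ (both non-NA) and whose score meets `min_score`, then
#' suppresses remaining candidates within the exclusion radius. Pass 2
#' re-classifies every accepted breakpoint with windows truncated at its
#' accepted neighbours (dropping breakpoints whose flanks then agree) and,
#' wherever the states of consecutive breakpoints (or the composition of a
#' flanking segment) are inconsistent, re-scans the offending interval with
#' the largest window width the surrounding accepted breakpoints allow,
#' accepting the best candidate; this recovers double crossovers closer
#' than one window width. Final breakpoints carry flanking informative
#' positions: the last site matching the left class and the first site
#' matching the right class.
#'
#' @param candidates output of [roaming_scan()] for the same codes.
#' @param codes data.frame with `pos` and `code`, sorted.
#' @param cfg a [breakpoint_config()].
#' @param chrom_len chromosome length in bp (defaults to the last typed
#'   position).
#' @return `data.table(left_bp, right_bp, midpoint, left_state,
#'   right_state, interval_bp, score, is_crossover)`; `is_crossover` is TRUE
#'   for P1<->P2 transitions (heterozygous-block boundaries are emitted as
#'   state changes but not counted as crossovers).
#' @export
resolve_breakpoints <- function(candidates, codes, cfg = breakpoint_config(),
                                chrom_len = NULL) {
  pos <- as.double(codes$pos)
  code <- as.character(codes$code)
  chrom_len <- chrom_len %||% if (length(pos)) max(pos) else 0
  empty <- data.table(left_bp = numeric(0), right_bp = numeric(0),
                      midpoint = numeric(0), left_state = character(0),
                      right_state = character(0), interval_bp = numeric(0),
                      score = numeric(0), is_crossover = logical(0))
  if (is.null(candidates) || nrow(candidates) == 0L) return(empty)
  cc <- par_cums(pos, code)

  # pass 1: greedy acceptance with exclusion radius
  cand <- as.data.table(candidates)
  ord <- order(-cand$score)
  suppressed <- rep(FALSE, nrow(cand))
  acc_x <- numeric(0)
  acc_s <- numeric(0)
  for (i in ord) {
    if (suppressed[i]) next
    if (cand$score[i] < cfg$min_score) break
    if (is.na(cand$classL[i]) || is.na(cand$classR[i]) ||
        cand$classL[i] == cand$classR[i]) next
    acc_x <- c(acc_x, cand$x[i])
    acc_s <- c(acc_s, cand$score[i])
    suppressed <- suppressed | abs(cand$x - cand$x[i]) <= cfg$exclusion
  }
  acc <- data.table(x = acc_x, score = acc_s)
  setorder(acc, x)

  relax <- 4L      # minimum sites per truncated window in pass 2
  run_min <- 4L    # consecutive opposite codes that flag a hidden block
  widths <- cfg$window / 2^(0:4)
  # majority parental class, used as the expected class when pass 1
  # accepted nothing on this chromosome
  n_all <- win_counts(cc, -Inf, Inf)
  if (n_all$n1 + n_all$n2 == 0L) return(empty)
  majority <- if (n_all$n1 >= n_all$n2) "P1" else "P2"

  banned <- numeric(0)  # dropped re-classified positions stay out
  for (iter in 1:40) {
    k <- nrow(acc)
    if (k > 0L) {
      # (2a) re-classify each accepted breakpoint with windows truncated at
      # its accepted neighbours; drop breakpoints whose flanks then agree
      lims_l <- c(0, acc$x[-k])
      lims_r <- c(acc$x[-1L], chrom_len)
      rs <- rescore_multiscale(acc$x, lims_l, lims_r, cc, cfg, relax,
                               widths)
      keep_bp <- !is.na(rs$classL) & !is.na(rs$classR) &
        rs$classL != rs$classR
      if (!all(keep_bp)) {
        banned <- c(banned, acc$x[!keep_bp])
        acc <- acc[keep_bp]
        next
      }
      acc[, `:=`(classL = rs$classL, classR = rs$classR)]
    }
    # (2b) find an inconsistent segment and re-scan it, shrinking the
    # window width if the full width cannot classify (close crossovers)
    k <- nrow(acc)
    bnd_x <- c(0, acc$x, chrom_len)
    if (k > 0L) {
      exp_l <- c(acc$classL[1L], acc$classR)  # expected class entering
      exp_r <- c(acc$classL, acc$classR[k])   # expected class leaving
    } else {
      exp_l <- exp_r <- majority
    }
    fixed <- FALSE
    for (s in seq_len(k + 1L)) {
      a <- bnd_x[s]
      b <- bnd_x[s + 1L]
      trigger <- exp_l[s] != exp_r[s]
      run_block <- NULL
      if (!trigger) {
        # consistent boundary states can still hide crossovers: the
        # segment composition must match the expected class ...
        w <- win_counts(cc, a, b)
        m <- classify_window(w$n1, w$n2, cfg, min_sites = 1L, nH = w$nH)
        trigger <- (w$n1 + w$n2) >= relax && (is.na(m) || m != exp_l[s])
        # ... and a run of opposite parental codes flags a short
        # double-crossover block that barely moves the composition; in an
        # expected-heterozygous segment single-parent runs occur by chance
        # (max run ~ log2 n), so the threshold adapts to the segment size
        if (!trigger && !is.na(exp_l[s])) {
          seg_idx <- which(cc$pp > a & cc$pp <= b)
          need_run <- if (exp_l[s] == "H") {
            max(run_min, ceiling(log2(length(seg_idx) + 1)) + 4L)
          } else run_min
          is1 <- diff(c(0, cc$c1))[seg_idx] == 1L
          for (opp in if (exp_l[s] == "H") list(is1, !is1) else
                 list(if (exp_l[s] == "P1") !is1 else is1)) {
            if (!any(opp)) next
            r <- rle(opp)
            if (max(r$lengths[r$values]) >= need_run) {
              trigger <- TRUE
              j <- which(r$values & r$lengths >= need_run)[1L]
              first <- sum(r$lengths[seq_len(j - 1L)]) + 1L
              run_block <- cc$pp[seg_idx[c(first,
                                           first + r$lengths[j] - 1L)]]
              break
            }
          }
        }
      }
      if (!trigger) next
      in_seg <- cand$x > a & cand$x < b & !(cand$x %in% acc$x) &
        !(cand$x %in% banned)
      if (!any(in_seg)) next
      xs <- cand$x[in_seg]
      if (!is.null(run_block)) {
        # short hidden block: insert both of its boundaries together,
        # windows truncated at the block so each side is pure
        xl <- suppressWarnings(max(xs[xs <= run_block[1L]]))
        xr <- suppressWarnings(min(xs[xs >= run_block[2L]]))
        if (is.finite(xl) && is.finite(xr) && xl < xr) {
          rl <- rescore_truncated(xl, a, xr, cc, cfg, relax)
          rr <- rescore_truncated(xr, xl, b, cc, cfg, relax)
          ok_l <- !is.na(rl$classL) && !is.na(rl$classR) &&
            rl$classL != rl$classR && rl$score > 0
          ok_r <- !is.na(rr$classL) && !is.na(rr$classR) &&
            rr$classL != rr$classR && rr$score > 0
          if (ok_l && ok_r) {
            acc <- rbind(acc[, .(x, score)],
                         data.table(x = c(xl, xr),
                                    score = c(rl$score, rr$score)))
            setorder(acc, x)
            fixed <- TRUE
            break
          }
        }
      }
      for (wd in widths) {
        rs2 <- rescore_truncated(xs, rep(a, length(xs)),
                                 rep(b, length(xs)), cc, cfg, relax, wd)
        ok <- !is.na(rs2$classL) & !is.na(rs2$classR) &
          rs2$classL != rs2$classR & rs2$score > 0
        if (any(ok)) {
          j <- which(ok)[which.max(rs2$score[ok])]
          acc <- rbind(acc[, .(x, score)],
                       data.table(x = xs[j], score = rs2$score[j]))
          setorder(acc, x)
          fixed <- TRUE
          break
        }
      }
      if (fixed) break
    }
    if (!fixed) break
  }
  if (!nrow(acc)) return(empty)

  # final classification with truncated windows (the loop can exit right
  # after an insertion at the iteration cap)
  k <- nrow(acc)
  rs <- rescore_multiscale(acc$x, c(0, acc$x[-k]),
                           c(acc$x[-1L], chrom_len), cc, cfg, relax,
                           widths)
  keep_bp <- !is.na(rs$classL) & !is.na(rs$classR) & rs$classL != rs$classR
  acc <- acc[keep_bp]
  if (!nrow(acc)) return(empty)
  acc[, `:=`(classL = rs$classL[keep_bp], classR = rs$classR[keep_bp])]

  # emit flanking informative positions; for parental-parental boundaries
  # the junction is refined to the minimum-misfit changepoint over the
  # local codes, so an isolated miscalled site near the junction cannot
  # drag the flanks off the true crossover
  k <- nrow(acc)
  bnd <- c(0, acc$x, chrom_len)
  out <- vector("list", k)
  for (j in seq_len(k)) {
    xL <- acc$x[j]
    cl <- acc$classL[j]
    cr <- acc$classR[j]
    lb <- rb <- NA_real_
    if (cl %in% c("P1", "P2") && cr %in% c("P1", "P2")) {
      sel <- which(pos > bnd[j] & pos <= bnd[j + 2L] & code != "H")
      if (length(sel) >= 2L) {
        sp <- pos[sel]
        scd <- code[sel]
        m <- length(sel)
        cR <- cumsum(scd == cr)
        cL <- cumsum(scd == cl)
        i_cut <- seq_len(m - 1L)
        cost <- cR[i_cut] + (cL[m] - cL[i_cut])
        best <- which(cost == min(cost))
        # tie-break: the cut closest to the accepted position
        cut <- best[which.min(abs((sp[best] + sp[best + 1L]) / 2 - xL))]
        lb <- sp[cut]
        rb <- sp[cut + 1L]
      }
    }
    if (is.na(lb)) {
      lsites <- pos[pos <= xL & code == cl]
      rsites <- pos[pos > xL & code == cr]
      lb <- if (length(lsites)) max(lsites) else max(pos[pos <= xL])
      rb <- if (length(rsites)) min(rsites) else min(pos[pos > xL])
    }
    out[[j]] <- data.table(
      left_bp = lb, right_bp = rb, midpoint = (lb + rb) / 2,
      left_state = cl, right_state = cr, interval_bp = rb - lb,
      score = acc$score[j],
      is_crossover = cl %in% c("P1", "P2") && cr %in% c("P1", "P2")
    )
  }
  rbindlist(out)
}

#' Detect crossover breakpoints for every line and chromosome
#'
#' Runs [roaming_scan()] and [resolve_breakpoints()] per line and
#' chromosome of a coded call table.
#'
#' @param calls a `coded_calls` table.
#' @param cfg a [breakpoint_config()].
#' @param genome optional [genome_spec()] supplying chromosome lengths
#'   (defaults to the `genome` attribute of `calls`).
#' @return `data.table(line, chrom, left_bp, right_bp, midpoint,
#'   left_state, right_state, interval_bp, score, is_crossover)`.
#' @export
detect_breakpoints <- function(calls, cfg = breakpoint_config(),
                               genome = NULL) {
  assert_coded_calls(calls)
  genome <- genome %||% attr(calls, "genome")
  calls <- as.data.table(calls)
  lens <- if (!is.null(genome)) {
    setNames(genome$lengths, genome$chroms)
  } else {
    unlist(lapply(split(calls$pos, calls$chrom), max))
  }
  res <- calls[, {
    cl <- .SD[order(pos)]
    cand <- roaming_scan(cl, cfg)
    resolve_breakpoints(cand, cl, cfg, chrom_len = lens[[.BY$chrom]])
  }, by = .(line, chrom)]
  res[]
}

#' Population recombination summary
#'
#' Totals detected crossovers, computes the reverse genetic-map length
#' `100 * B / n` centiMorgans (B crossovers over n lines, the RIL-scale
#' convention), interval-length statistics, and a positional histogram of
#' crossover midpoints in 20 equal chromosome-relative slices.
#'
#' @param breakpoints breakpoint table from [detect_breakpoints()] (only
#'   rows with `is_crossover` enter the crossover count and histogram).
#' @param n_lines number of lines in the population.
#' @param genome a [genome_spec()] (for chromosome lengths).
#' @param n_slices number of relative-position histogram slices (default
#'   20).
#' @return list with `n_crossovers`, `n_lines`, `map_length_cM`,
#'   `median_interval_bp`, `mean_interval_bp`, and `histogram`
#'   (`data.table(chrom, slice, rel_start, rel_end, count)`).
#' @export
summarize_recombination <- function(breakpoints, n_lines, genome = NULL,
                                    n_slices = 20L) {
  if (n_lines <= 0) stop("n_lines must be > 0")
  bp <- as.data.table(breakpoints)
  xo <- if (nrow(bp)) bp[is_crossover == TRUE] else bp
  B <- nrow(xo)
  hist_dt <- NULL
  if (!is.null(genome) && B > 0) {
    lens <- setNames(genome$lengths, genome$chroms)
    xo2 <- copy(xo)
    xo2[, rel_pos := midpoint / lens[chrom]]
    breaks <- seq(0, 1, length.out = n_slices + 1L)
    xo2[, slice := pmin(findInterval(rel_pos, breaks,
                                     rightmost.closed = TRUE), n_slices)]
    grid <- CJ(chrom = genome$chroms, slice = seq_len(n_slices))
    hist_dt <- xo2[, .(count = .N), by = .(chrom, slice)][grid,
                                                          on = c("chrom",
                                                                 "slice")]
    hist_dt[is.na(count), count := 0L]
    hist_dt[, `:=`(rel_start = (slice - 1) / n_slices,
                   rel_end = slice / n_slices)]
    setorder(hist_dt, chrom, slice)
  }
  list(
    n_crossovers = B,
    n_lines = n_lines,
    map_length_cM = 100 * B / n_lines,
    median_interval_bp = if (B) median(xo$interval_bp) else NA_real_,
    mean_interval_bp = if (B) mean(xo$interval_bp) else NA_real_,
    histogram = hist_dt
  )
}
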