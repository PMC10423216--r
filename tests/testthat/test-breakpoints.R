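# Independent oracle: naive re-implementation of the paired-window score,
# evaluated by direct counting (no cumulative sums).
naive_score <- function(pos, code, x, cfg) {
  par <- code != "H"
  inL <- par & pos > x - cfg$window & pos <= x
  inR <- par & pos > x & pos <= x + cfg$window
  n1L <- sum(code[inL] == "P1"); n2L <- sum(inL) - n1L
  n1R <- sum(code[inR] == "P1"); n2R <- sum(inR) - n1R
  cl <- function(n1, n2) {
    n <- n1 + n2
    if (n < cfg$min_sites) return(NA_character_)
    p <- n1 / n
    if (p >= cfg$purity) "P1"
    else if (p <= 1 - cfg$purity) "P2"
    else if (p >= cfg$h_band[1] && p <= cfg$h_band[2]) "H"
    else NA_character_
  }
  if (is.na(cl(n1L, n2L)) || is.na(cl(n1R, n2R))) return(0)
  nL <- n1L + n2L; nR <- n1R + n2R
  abs(n1L / nL - n1R / nR) * sqrt(nL * nR / (nL + nR)) /
    sqrt(cfg$min_sites)
}

test_that("window profiles classify the four categories", {
  cfg <- breakpoint_config()
  codes <- data.frame(pos = seq_len(20) * 1e5, code = rep("P1", 20))
  pr <- window_profile(codes, 2.1e6, "left", cfg)
  expect_equal(pr$class, "P1")
  expect_equal(pr$p, 1.0)
  codes2 <- data.frame(pos = seq_len(20) * 1e5,
                       code = c(rep("P1", 11), rep("P2", 9)))
  pr2 <- window_profile(codes2, 2.1e6, "left", cfg)
  expect_equal(pr2$class, "H")  # p = 0.55 within the 1:1 band
  codes3 <- data.frame(pos = seq_len(5) * 1e5, code = rep("P1", 5))
  expect_true(is.na(window_profile(codes3, 6e5, "left", cfg)$class))
})

test_that("a homogeneous line yields no candidates", {
  cand <- roaming_scan(data.frame(pos = seq_len(50) * 1e5,
                                  code = rep("P1", 50)))
  expect_equal(nrow(cand), 0)
})

test_that("roaming scores equal exhaustive midpoint evaluation", {
  cfg <- breakpoint_config()
  # perfect switch: 30 P1 then 30 P2 at 100 kb spacing
  pos <- seq_len(60) * 1e5
  code <- c(rep("P1", 30), rep("P2", 30))
  cand <- roaming_scan(data.frame(pos = pos, code = code), cfg)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$x, (pos[30] + pos[31]) / 2)
  # oracle over every inter-site midpoint
  mids <- (pos[-1] + pos[-60]) / 2
  oracle <- vapply(mids, function(m) naive_score(pos, code, m, cfg), 0)
  expect_equal(cand$score, max(oracle))
  expect_equal(cand$x, mids[which.max(oracle)])
  # noisy case: scores at every differing midpoint must match the oracle
  set.seed(8)
  code2 <- code
  code2[sample(60, 6)] <- sample(c("P1", "P2", "H"), 6, replace = TRUE)
  cand2 <- roaming_scan(data.frame(pos = pos, code = code2), cfg)
  for (r in seq_len(nrow(cand2))) {
    expect_equal(cand2$score[r], naive_score(pos, code2, cand2$x[r], cfg))
  }
})

test_that("a single flipped site scores below the acceptance threshold", {
  cfg <- breakpoint_config()
  code <- rep("P1", 60)
  code[30] <- "P2"
  cand <- roaming_scan(data.frame(pos = seq_len(60) * 1e5, code = code),
                       cfg)
  expect_true(all(cand$score < cfg$min_score))
  expect_equal(nrow(resolve_breakpoints(cand,
                                        data.frame(pos = seq_len(60) * 1e5,
                                                   code = code), cfg)), 0)
})

test_that("empty candidate lists resolve to no breakpoints", {
  codes <- data.frame(pos = seq_len(10) * 1e5, code = rep("P1", 10))
  expect_equal(nrow(resolve_breakpoints(roaming_scan(codes), codes)), 0)
})

test_that("well-separated crossovers are each localized between their
          flanking markers", {
  d <- sim_dataset(n_lines = 45, n_chrom = 1, len = 100e6, coverage = 3,
                   map_length = 1, seed = 33)
  bp <- detect_breakpoints(d$calls)
  tx <- d$truth$breakpoints[is_crossover == TRUE]
  two_far <- tx[, .N, by = .(line, chrom)][N == 2]
  checked <- 0
  for (r in seq_len(nrow(two_far))) {
    li <- two_far$line[r]
    tpos <- tx[line == li, sort(pos)]
    if (diff(tpos) < 2 * 6.5e6) next
    if (nrow(d$truth$breakpoints[line == li & !is_crossover])) next
    dx <- bp[line == li & is_crossover == TRUE]
    expect_equal(nrow(dx), 2)
    for (k in 1:2) {
      expect_true(any(dx$left_bp <= tpos[k] & dx$right_bp >= tpos[k]))
    }
    checked <- checked + 1
  }
  expect_gte(checked, 3)
})

test_that("double crossovers within one window width are recovered", {
  # two crossovers ~2 Mb apart (< 6.5 Mb window) at 20 kb typed spacing
  set.seed(91)
  recovered <- 0
  n_rep <- 40
  for (i in seq_len(n_rep)) {
    pos <- sort(sample(seq(2e4, 40e6, by = 2e4), 1500))
    u <- 15e6 + runif(1, -2e6, 2e6)
    v <- u + 2e6 + runif(1, -5e5, 5e5)
    code <- ifelse(pos > u & pos <= v, "P2", "P1")
    # sprinkle read errors
    flip <- runif(length(code)) < 0.002
    code[flip] <- ifelse(code[flip] == "P1", "P2", "P1")
    codes <- data.frame(pos = pos, code = code)
    res <- resolve_breakpoints(roaming_scan(codes), codes,
                               chrom_len = 40e6)
    res <- res[res$is_crossover, ]
    ok <- nrow(res) == 2 &&
      any(res$left_bp <= u & res$right_bp >= u) &&
      any(res$left_bp <= v & res$right_bp >= v)
    recovered <- recovered + ok
  }
  expect_gte(recovered / n_rep, 0.9)
})

test_that("the score and the detection are symmetric under P1/P2 swap", {
  d <- sim_dataset(n_lines = 6, n_chrom = 1, len = 50e6, coverage = 2,
                   seed = 55)
  calls <- data.table::copy(d$calls)
  bp1 <- detect_breakpoints(calls)
  swapped <- data.table::copy(calls)
  swapped[, code := data.table::fcase(code == "P1", "P2",
                                      code == "P2", "P1",
                                      default = "H")]
  data.table::setattr(swapped, "lines", attr(calls, "lines"))
  data.table::setattr(swapped, "genome", attr(calls, "genome"))
  data.table::setattr(swapped, "class", class(calls))
  bp2 <- detect_breakpoints(swapped)
  expect_equal(bp1$midpoint, bp2$midpoint)
  swap <- c(P1 = "P2", P2 = "P1", H = "H")
  expect_equal(unname(swap[bp1$left_state]), bp2$left_state)
  # the score itself is exactly symmetric candidate by candidate
  one <- calls[line == attr(calls, "lines")[1] & chrom == "chr1"]
  sw <- data.frame(pos = one$pos,
                   code = unname(swap[one$code]))
  expect_equal(roaming_scan(as.data.frame(one))$score,
               roaming_scan(sw)$score)
})

test_that("the reverse map length follows 100 * B / n", {
  s <- summarize_recombination(
    data.table::data.table(is_crossover = rep(TRUE, 10), midpoint = 1:10,
                           interval_bp = rep(1e5, 10), chrom = "chr1"),
    n_lines = 4
  )
  expect_equal(s$map_length_cM, 250)
  s0 <- summarize_recombination(
    data.table::data.table(is_crossover = logical(0),
                           midpoint = numeric(0),
                           interval_bp = numeric(0), chrom = character(0)),
    n_lines = 4
  )
  expect_equal(s0$map_length_cM, 0)
  expect_true(is.na(s0$median_interval_bp))
  expect_error(summarize_recombination(NULL, 0), "n_lines")
})

test_that("the positional histogram shows the desert", {
  d <- sim_dataset(n_lines = 30, n_chrom = 1, len = 100e6, coverage = 2,
                   seed = 77)
  bp <- detect_breakpoints(d$calls)
  s <- summarize_recombination(bp, 30, d$genome)
  h <- s$histogram
  central <- h[slice > 5 & slice <= 15, sum(count)]
  expect_lte(central, 0.02 * sum(h$count))
})
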