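# Parental-origin HMM imputation of missing site genotypes.
#
# Three hidden states (P1, P2, H) over the typed sites of one line and
# chromosome. The switch probability between parental states over an
# inter-site distance d is t(d) = (1 - exp(-2 d / D)) / 2 with D the
# recombination distance scale (default 1 Mb, the distance over which a
# crossover becomes plausible); entry into and out of the heterozygous
# state is scaled by the heterozygous prior.

#' Imputation settings
#'
#' @param error assumed genotyping error rate of the observed codes
#'   (default 0.01; deliberately distinct from any simulator read error so
#'   that mild model misspecification is the normal case).
#' @param recomb_dist recombination distance scale D in bp (default 1e6).
#' @param het_prior prior probability of the heterozygous state
#'   (default 0.03, the residual-heterozygosity expectation of an F6 RIL).
#' @param h_emission probability that a site whose true state is
#'   heterozygous is observed as code H rather than a single parental code
#'   (default 0.1; at skim coverage most typed sites carry one read, which
#'   cannot show both alleles).
#' @param resolve_conflicts replace observed codes that disagree with the
#'   decoded state (default TRUE); when FALSE disagreements are only
#'   counted.
#' @param mask_frac hold-out mask fraction for [holdout_accuracy()]
#'   (default 0.03).
#' @param method `"viterbi"` (default; hard assignment) or `"posterior"`
#'   (forward-backward posterior mode).
#' @param seed seed for hold-out masking.
#' @return an object of class `impute_config`.
#' @export
impute_config <- function(error = 0.01, recomb_dist = 1e6,
                          het_prior = 0.03, h_emission = 0.1,
                          resolve_conflicts = TRUE, mask_frac = 0.03,
                          method = c("viterbi", "posterior"), seed = 1L) {
  assert_scalar_num(error, "error", 0, 0.5, strict_lower = TRUE,
                    strict_upper = TRUE)
  assert_scalar_num(recomb_dist, "recomb_dist", 0, strict_lower = TRUE)
  assert_scalar_num(het_prior, "het_prior", 0, 0.5, strict_upper = TRUE)
  assert_scalar_num(h_emission, "h_emission", 0, 1, strict_upper = TRUE)
  assert_scalar_num(mask_frac, "mask_frac", 0, 1)
  structure(list(error = error, recomb_dist = recomb_dist,
                 het_prior = het_prior, h_emission = h_emission,
                 resolve_conflicts = isTRUE(resolve_conflicts),
                 mask_frac = mask_frac, method = match.arg(method),
                 seed = as.integer(seed)),
            class = "impute_config")
}

# Emission matrix rows = states (P1, P2, H), cols = observed codes.
# In a parental state the opposite code appears with the full error rate
# and an observed H (which needs two reads, one of them wrong) with e^2.
#' @noRd
emission_matrix <- function(cfg) {
  e <- cfg$error
  q <- cfg$h_emission
  m <- rbind(
    P1 = c(1 - e - e^2, e, e^2),
    P2 = c(e, 1 - e - e^2, e^2),
    H  = c((1 - q) / 2, (1 - q) / 2, q)
  )
  colnames(m) <- CODES
  m
}

# Transition matrix for one inter-site distance d.
#' @noRd
transition_matrix <- function(d, cfg) {
  t <- 0.5 * (1 - exp(-2 * d / cfg$recomb_dist))
  ph <- cfg$het_prior
  rbind(
    c(1 - t, t * (1 - ph), t * ph),
    c(t * (1 - ph), 1 - t, t * ph),
    c(t / 2, t / 2, 1 - t)
  )
}

#' Decode the parental-origin state path of one line on one chromosome
#'
#' Maximum a-posteriori state path (Viterbi, log domain, ties broken toward
#' the previous state) or forward-backward posterior mode, over the typed
#' sites only.
#'
#' @param codes data.frame with `pos` (strictly increasing) and `code` for
#'   one line on one chromosome.
#' @param cfg an [impute_config()].
#' @return character vector of decoded states (`"P1"`, `"P2"`, `"H"`), one
#'   per typed site.
#' @export
viterbi_decode <- function(codes, cfg = impute_config()) {
  pos <- as.double(codes$pos)
  obs <- match(as.character(codes$code), CODES)
  n <- length(pos)
  if (n == 0L) stop("no typed sites to decode")
  if (anyNA(obs)) stop("invalid codes in input")
  if (n > 1L && any(diff(pos) <= 0)) {
    stop("positions must be strictly increasing")
  }
  E <- log(emission_matrix(cfg))
  init <- log(c((1 - cfg$het_prior) / 2, (1 - cfg$het_prior) / 2,
                cfg$het_prior))
  if (cfg$method == "posterior") {
    return(CODES[posterior_mode(pos, obs, cfg)])
  }
  delta <- init + E[, obs[1L]]
  psi <- matrix(0L, 3L, n)
  if (n > 1L) {
    for (tstep in 2:n) {
      A <- log(transition_matrix(pos[tstep] - pos[tstep - 1L], cfg))
      new_delta <- numeric(3L)
      for (j in 1:3) {
        s <- delta + A[, j]
        # tie-break toward staying in state j
        iprev <- if (s[j] >= max(s) - 1e-12) j else which.max(s)
        psi[j, tstep] <- iprev
        new_delta[j] <- s[iprev] + E[j, obs[tstep]]
      }
      delta <- new_delta
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1L) {
    for (tstep in n:2) path[tstep - 1L] <- psi[path[tstep], tstep]
  }
  CODES[path]
}

#' @noRd
posterior_mode <- function(pos, obs, cfg) {
  n <- length(pos)
  E <- emission_matrix(cfg)
  init <- c((1 - cfg$het_prior) / 2, (1 - cfg$het_prior) / 2, cfg$het_prior)
  fwd <- matrix(0, 3L, n)
  f <- init * E[, obs[1L]]
  fwd[, 1L] <- f / sum(f)
  if (n > 1L) {
    for (tstep in 2:n) {
      A <- transition_matrix(pos[tstep] - pos[tstep - 1L], cfg)
      f <- drop(crossprod(A, fwd[, tstep - 1L])) * E[, obs[tstep]]
      fwd[, tstep] <- f / sum(f)
    }
  }
  bwd <- matrix(0, 3L, n)
  bwd[, n] <- 1
  if (n > 1L) {
    for (tstep in (n - 1L):1L) {
      A <- transition_matrix(pos[tstep + 1L] - pos[tstep], cfg)
      b <- drop(A %*% (E[, obs[tstep + 1L]] * bwd[, tstep + 1L]))
      bwd[, tstep] <- b / sum(b)
    }
  }
  apply(fwd * bwd, 2L, which.max)
}

# Predicted state at arbitrary positions given decoded states at typed
# positions: nearest typed neighbour, ties toward the left.
#' @noRd
predict_states <- function(at, typed_pos, states) {
  i <- findInterval(at, typed_pos)
  i[i == 0L] <- 1L
  left <- typed_pos[i]
  right <- typed_pos[pmin(i + 1L, length(typed_pos))]
  use_right <- (at - left) > (right - at)
  out <- states[i]
  out[use_right] <- states[pmin(i + 1L, length(typed_pos))][use_right]
  out
}

#' Impute every key site within each line's typed span
#'
#' Decodes the state path per line and chromosome and assigns the decoded
#' state (of the nearest typed site) to every key site between the first
#' and last typed site; key sites outside the typed span remain missing.
#' Observed codes that disagree with the decoded state are counted as
#' conflicts and, when `resolve_conflicts` is on, replaced by the decoded
#' state.
#'
#' @param calls a `coded_calls` table.
#' @param key the `parent_key` (supplies the full site list).
#' @param cfg an [impute_config()].
#' @return list with `calls` (completed `coded_calls`), `n_conflicts`,
#'   `n_imputed`, and `missing_frac` (fraction of key sites x lines still
#'   missing after imputation).
#' @export
impute_matrix <- function(calls, key, cfg = impute_config()) {
  assert_coded_calls(calls)
  stopifnot(inherits(key, "parent_key"))
  calls <- as.data.table(calls)
  lines <- attr(calls, "lines") %||% unique(calls$line)
  key_pos <- split(key$pos, key$chrom)
  out <- list()
  n_conflicts <- 0L
  n_imputed <- 0L
  k <- 0L
  for (li in lines) {
    for (ci in names(key_pos)) {
      cl <- calls[line == li & chrom == ci][order(pos)]
      k <- k + 1L
      if (nrow(cl) == 0L) next
      st <- viterbi_decode(cl, cfg)
      n_conflicts <- n_conflicts + sum(st != cl$code)
      obs_code <- if (cfg$resolve_conflicts) st else cl$code
      kp <- key_pos[[ci]]
      span <- kp[kp >= cl$pos[1L] & kp <= cl$pos[nrow(cl)]]
      imp_pos <- setdiff(span, cl$pos)
      n_imputed <- n_imputed + length(imp_pos)
      out[[k]] <- data.table(
        line = li, chrom = ci,
        pos = c(cl$pos, imp_pos),
        code = c(obs_code, predict_states(imp_pos, cl$pos, st))
      )
    }
  }
  res <- rbindlist(out)
  setkey(res, line, chrom, pos)
  setattr(res, "lines", lines)
  if (!is.null(attr(calls, "genome"))) {
    setattr(res, "genome", attr(calls, "genome"))
  }
  setattr(res, "class", c("coded_calls", class(res)))
  total <- nrow(key) * length(lines)
  list(calls = res[], n_conflicts = n_conflicts, n_imputed = n_imputed,
       missing_frac = 1 - nrow(res) / total)
}

#' Hold-out validation of imputation accuracy
#'
#' Masks `mask_frac` of each line's non-missing codes independently on each
#' chromosome (uniformly at random, seeded), re-decodes the remaining
#' codes, predicts the masked positions, and scores them against the
#' held-out observed codes. The overall accuracy is the mean over lines of
#' the per-line accuracy, matching the convention of averaging per-RIL
#' accuracies.
#'
#' @param calls a `coded_calls` table.
#' @param cfg an [impute_config()] (uses `mask_frac` and `seed`).
#' @return list with `overall_accuracy`, `per_line`
#'   (`data.table(line, masked, correct, accuracy)`), `per_chrom`, and
#'   `n_skipped` (line/chromosome pairs with no maskable site).
#' @export
holdout_accuracy <- function(calls, cfg = impute_config()) {
  assert_coded_calls(calls)
  if (cfg$mask_frac <= 0 || cfg$mask_frac >= 1) {
    stop("mask_frac must be in (0, 1)")
  }
  calls <- as.data.table(calls)
  set.seed(derive_seed(cfg$seed, 5L))
  res <- list()
  k <- 0L
  n_skipped <- 0L
  combos <- unique(calls[, .(line, chrom)])
  for (r in seq_len(nrow(combos))) {
    li <- combos$line[r]
    ci <- combos$chrom[r]
    cl <- calls[line == li & chrom == ci][order(pos)]
    m <- floor(cfg$mask_frac * nrow(cl))
    if (m < 1L || nrow(cl) - m < 2L) {
      n_skipped <- n_skipped + 1L
      next
    }
    idx <- sort(sample.int(nrow(cl), m))
    train <- cl[-idx]
    st <- viterbi_decode(train, cfg)
    pred <- predict_states(cl$pos[idx], train$pos, st)
    k <- k + 1L
    res[[k]] <- data.table(line = li, chrom = ci, masked = m,
                           correct = sum(pred == cl$code[idx]))
  }
  if (!k) stop("no line/chromosome had enough typed sites to mask")
  res <- rbindlist(res)
  per_line <- res[, .(masked = sum(masked), correct = sum(correct)),
                  by = line]
  per_line[, accuracy := correct / masked]
  per_chrom <- res[, .(masked = sum(masked), correct = sum(correct)),
                   by = chrom]
  per_chrom[, accuracy := correct / masked]
  list(overall_accuracy = mean(per_line$accuracy),
       per_line = per_line[], per_chrom = per_chrom[],
       n_skipped = n_skipped)
}
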