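# End-to-end orchestration from a single JSON configuration, with stage
# toggles, a run manifest (checksums + timings) and plain files between
# stages so every stage can also be run on its own.

#' @noRd
pipeline_schema <- function() {
  list(
    seed = NULL, out_dir = NULL, log_level = NULL,
    stages = c("simulate", "screen", "bins", "breakpoints", "impute",
               "holdout", "map", "scan"),
    inputs = c("key_tsv", "calls_tsv", "chrom_lengths_tsv", "phenotype_tsv"),
    simulate = c("n_chroms", "chrom_length", "snp_density", "n_lines",
                 "generations", "map_length", "desert_frac", "arm_shape",
                 "coverage", "error", "obligate_xo", "p1_ref_prop",
                 "qtl_chrom", "qtl_pos", "qtl_effect", "sigma"),
    screen = c("max_h_frac"),
    bins = c("threshold", "min_sites", "bin_size"),
    breakpoints = c("window", "min_sites", "purity", "min_score",
                    "exclusion"),
    impute = c("error", "recomb_dist", "het_prior", "h_emission",
               "resolve_conflicts", "mask_frac", "method"),
    map = c("seg_p", "max_missing", "ril_correction"),
    scan = c("permutations", "alpha", "major_pve", "h_handling",
             "subsample_frac", "fdr_level", "min_lines", "trait")
  )
}

#' Validate a pipeline configuration
#'
#' Reads a JSON configuration (or takes an equivalent list), rejects any
#' unknown key by name, checks nested settings through the module
#' constructors, and fills in all documented defaults. Either a `simulate`
#' block or `inputs` paths (which must exist) are required.
#'
#' @param config path to a JSON file, or a list.
#' @return the validated, fully-defaulted configuration (class
#'   `pipeline_config`).
#' @export
validate_config <- function(config) {
  cfg <- if (is.character(config)) {
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else config
  schema <- pipeline_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (sect in intersect(names(cfg), names(schema))) {
    allowed <- schema[[sect]]
    if (!is.character(allowed)) next
    bad <- setdiff(names(cfg[[sect]]), allowed)
    if (length(bad)) {
      stop(sprintf("unknown key(s) in '%s': %s", sect,
                   paste(bad, collapse = ", ")))
    }
  }
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    stop("configuration needs either a 'simulate' block or 'inputs' paths")
  }
  if (!is.null(cfg$inputs)) {
    for (p in unlist(cfg$inputs)) {
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "skimbin_out"
  all_stages <- pipeline_schema()$stages
  cfg$stages <- as.list(setNames(
    lapply(all_stages, function(s) isTRUE(cfg$stages[[s]] %||% TRUE)),
    all_stages
  ))
  if (is.null(cfg$simulate)) cfg$stages$simulate <- FALSE
  # build module configs now so invalid values fail at validation time
  sm <- cfg$simulate
  if (!is.null(sm)) {
    cfg$sim_cfg <- sim_config(
      n_lines = sm$n_lines %||% 300, generations = sm$generations %||% 6,
      map_length = sm$map_length %||% 1,
      desert_frac = sm$desert_frac %||% 0.5,
      arm_shape = sm$arm_shape %||% 0.5, coverage = sm$coverage %||% 0.03,
      error = sm$error %||% 0.002,
      obligate_xo = isTRUE(sm$obligate_xo), seed = cfg$seed
    )
    cfg$genome <- genome_spec(
      paste0("chr", seq_len(sm$n_chroms %||% 7)),
      rep(sm$chrom_length %||% 100e6, sm$n_chroms %||% 7),
      sm$snp_density %||% (1 / 20e3)
    )
  }
  cfg$screen_cfg <- cfg$screen$max_h_frac %||% 0.10
  cfg$bin_cfg <- do.call(bin_config, cfg$bins %||% list())
  cfg$bp_cfg <- do.call(breakpoint_config, cfg$breakpoints %||% list())
  imp <- cfg$impute %||% list()
  imp$seed <- cfg$seed
  cfg$imp_cfg <- do.call(impute_config, imp)
  cfg$map_cfg <- do.call(map_config, cfg$map %||% list())
  sc <- cfg$scan %||% list()
  trait_name <- sc$trait
  sc$trait <- NULL
  sc$seed <- cfg$seed
  cfg$scan_cfg <- do.call(scan_config, sc)
  cfg$trait <- trait_name
  structure(cfg, class = "pipeline_config")
}

#' @noRd
stage_record <- function(manifest, name, t0, files) {
  files <- files[file.exists(files)]
  manifest$stages[[name]] <- list(
    seconds = round(as.numeric(Sys.time()) - t0, 2),
    outputs = as.list(tools::md5sum(files))
  )
  manifest
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in dependency order (simulate or load ->
#' screen -> bins -> breakpoints -> impute/holdout -> map -> scan), writing
#' each stage's outputs under `out_dir` before the next stage starts, and
#' returns a manifest with per-stage wall-clock times and output MD5
#' checksums. Re-running with the same configuration reproduces identical
#' checksums.
#'
#' @param cfg a validated [validate_config()] result (or a path/list,
#'   which is validated first).
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) cfg <- validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  manifest <- list(
    tool = "skimbin",
    version = as.character(utils::packageVersion("skimbin")),
    seed = cfg$seed, stages = list()
  )
  msg <- function(...) message("[skimbin] ", sprintf(...))

  key <- NULL; calls <- NULL; truth <- NULL; pheno <- NULL
  if (cfg$stages$simulate) {
    t0 <- as.numeric(Sys.time())
    msg("simulate: %d lines, %d chromosomes", cfg$sim_cfg$n_lines,
        length(cfg$genome$chroms))
    key <- simulate_parents(cfg$genome, seed = cfg$seed,
                            p1_ref_prop = cfg$simulate$p1_ref_prop %||%
                              0.875)
    truth <- simulate_ril_population(key, cfg$sim_cfg)
    calls <- simulate_skim_calls(truth, key, cfg$sim_cfg)
    write_parent_key_tsv(key, out("parent_key.tsv"))
    write_coded_calls_tsv(calls, out("coded_calls.tsv"))
    fwrite(truth$breakpoints, out("truth_breakpoints.tsv"), sep = "\t")
    if (!is.null(cfg$simulate$qtl_chrom)) {
      qs <- qtl_spec(
        loci = data.table(chrom = cfg$simulate$qtl_chrom,
                          pos = cfg$simulate$qtl_pos,
                          effect = cfg$simulate$qtl_effect),
        sigma = cfg$simulate$sigma %||% 1
      )
      pheno <- simulate_phenotypes(truth, qs, seed = cfg$seed)
      write_phenotype_tsv(pheno, out("phenotypes.tsv"))
    }
    manifest <- stage_record(manifest, "simulate", t0,
                             c(out("parent_key.tsv"),
                               out("coded_calls.tsv"),
                               out("truth_breakpoints.tsv"),
                               out("phenotypes.tsv")))
  } else {
    key <- read_parent_key_tsv(cfg$inputs$key_tsv)
    calls <- read_coded_calls_tsv(cfg$inputs$calls_tsv)
    if (!is.null(cfg$inputs$chrom_lengths_tsv)) {
      cl <- fread(cfg$inputs$chrom_lengths_tsv)
      genome <- genome_spec(cl$chrom, cl$length,
                            max(nrow(key) / sum(cl$length), 1e-9))
      setattr(calls, "genome", genome)
      setattr(key, "genome", genome)
    }
    if (!is.null(cfg$inputs$phenotype_tsv)) {
      pheno <- read_phenotype_tsv(cfg$inputs$phenotype_tsv)
    }
  }
  genome <- attr(calls, "genome")
  if (is.null(genome)) stop("no chromosome lengths available")

  if (cfg$stages$screen) {
    t0 <- as.numeric(Sys.time())
    scr <- screen_heterozygous_lines(calls, cfg$screen_cfg)
    msg("screen: %d of %d lines retained", sum(scr$qc$retained),
        nrow(scr$qc))
    fwrite(scr$qc, out("line_qc.tsv"), sep = "\t")
    calls <- scr$calls
    manifest <- stage_record(manifest, "screen", t0, out("line_qc.tsv"))
  }

  bg <- NULL
  if (cfg$stages$bins) {
    t0 <- as.numeric(Sys.time())
    bins <- make_bins(genome, cfg$bin_cfg)
    bg <- bin_matrix(calls, bins, cfg$bin_cfg)
    msg("bins: %d bins x %d lines", ncol(bg$geno), nrow(bg$geno))
    write_bin_matrix_tsv(bg, out("bin_matrix.tsv"), out("bin_counts.tsv"))
    manifest <- stage_record(manifest, "bins", t0,
                             c(out("bin_matrix.tsv"), out("bin_counts.tsv")))
  }

  if (cfg$stages$breakpoints) {
    t0 <- as.numeric(Sys.time())
    bp <- detect_breakpoints(calls, cfg$bp_cfg, genome)
    summ <- summarize_recombination(bp, length(attr(calls, "lines")),
                                    genome)
    msg("breakpoints: %d crossovers, reverse map %.0f cM",
        summ$n_crossovers, summ$map_length_cM)
    fwrite(bp, out("breakpoints.tsv"), sep = "\t")
    jsonlite::write_json(summ[c("n_crossovers", "n_lines", "map_length_cM",
                                "median_interval_bp", "mean_interval_bp")],
                         out("recombination_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- stage_record(manifest, "breakpoints", t0,
                             c(out("breakpoints.tsv"),
                               out("recombination_summary.json")))
  }

  imputed <- NULL
  if (cfg$stages$impute) {
    t0 <- as.numeric(Sys.time())
    imp <- impute_matrix(calls, key, cfg$imp_cfg)
    imputed <- imp$calls
    msg("impute: %d sites imputed, %d conflicts, %.1f%% still missing",
        imp$n_imputed, imp$n_conflicts, 100 * imp$missing_frac)
    write_coded_calls_tsv(imputed, out("imputed_calls.tsv"))
    manifest <- stage_record(manifest, "impute", t0,
                             out("imputed_calls.tsv"))
  }
  if (cfg$stages$holdout) {
    t0 <- as.numeric(Sys.time())
    ho <- holdout_accuracy(calls, cfg$imp_cfg)
    msg("holdout: mean accuracy %.3f", ho$overall_accuracy)
    jsonlite::write_json(list(overall_accuracy = ho$overall_accuracy,
                              n_skipped = ho$n_skipped),
                         out("holdout.json"), auto_unbox = TRUE,
                         digits = NA)
    fwrite(ho$per_line, out("holdout_per_line.tsv"), sep = "\t")
    manifest <- stage_record(manifest, "holdout", t0,
                             c(out("holdout.json"),
                               out("holdout_per_line.tsv")))
  }

  if (cfg$stages$map && !is.null(bg)) {
    t0 <- as.numeric(Sys.time())
    gm <- build_map(bg, cfg$map_cfg)
    msg("map: %.1f cM corrected (%.1f uncorrected)", gm$total_cM,
        gm$total_uncorrected_cM)
    fwrite(gm$map, out("genetic_map.tsv"), sep = "\t")
    fwrite(gm$filter$log, out("marker_filter.tsv"), sep = "\t")
    manifest <- stage_record(manifest, "map", t0,
                             c(out("genetic_map.tsv"),
                               out("marker_filter.tsv")))
  }

  if (cfg$stages$scan && !is.null(bg) && !is.null(pheno)) {
    t0 <- as.numeric(Sys.time())
    y <- pool_phenotype(pheno, cfg$trait)
    sm <- single_marker_scan(bg, y, cfg$scan_cfg)
    th <- permutation_threshold(bg, y, cfg$scan_cfg)
    sm[, significant := !is.na(LOD) & LOD >= th$threshold]
    msg("scan: threshold %.2f, %d significant bins", th$threshold,
        sum(sm$significant))
    fwrite(sm, out("scan.tsv"), sep = "\t")
    jsonlite::write_json(
      list(threshold = th$threshold,
           significant = sm[significant == TRUE, bin]),
      out("scan_summary.json"), auto_unbox = TRUE, digits = NA
    )
    manifest <- stage_record(manifest, "scan", t0,
                             c(out("scan.tsv"), out("scan_summary.json")))
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
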