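#' Pipeline configuration
#'
#' Collects every stage parameter in one object. Either point `coverage_tsv`
#' (controls + tumors in one table, control samples named in `controls`) and
#' `clinical_csv` at data on disk, or set `simulate = cohort_spec(...)` to run
#' on a synthetic cohort. A YAML file with the same field names can be loaded
#' with `pipeline_config(yaml = path)`.
#'
#' @param genome `"hg19"`, a `cin_genome` tibble, or a genome-model TSV path.
#' @param bin_size Bin width (bp).
#' @param simulate Optional [cohort_spec()]; when set, input paths are ignored.
#' @param coverage_tsv,clinical_csv,controls On-disk inputs (see above).
#' @param qc A [qc_config()].
#' @param alpha,n_perm,min_width,merge_sd Segmentation parameters.
#' @param z_min,use_abs,units CIN-score parameters.
#' @param cutoff `"derive"` (maximally selected rank statistics on the cohort)
#'   or a fixed numeric cutoff.
#' @param out_dir Output directory (created).
#' @param seed Integer seed recorded in the manifest and fanned out to stages.
#' @param yaml Optional YAML path; fields found there override defaults.
#' @return List with class `pipeline_config`.
#' @export
pipeline_config <- function(genome = "hg19", bin_size = 200000,
                            simulate = NULL, coverage_tsv = NULL,
                            clinical_csv = NULL, controls = NULL,
                            qc = qc_config(),
                            alpha = 0.01, n_perm = 1000, min_width = 3,
                            merge_sd = 1.5,
                            z_min = 2, use_abs = TRUE, units = "Mb",
                            cutoff = "derive",
                            out_dir = tempfile("cinrun"), seed = 1,
                            yaml = NULL) {
  cfg <- list(genome = genome, bin_size = bin_size, simulate = simulate,
              coverage_tsv = coverage_tsv, clinical_csv = clinical_csv,
              controls = controls, qc = qc, alpha = alpha, n_perm = n_perm,
              min_width = min_width, merge_sd = merge_sd, z_min = z_min,
              use_abs = use_abs, units = units, cutoff = cutoff,
              out_dir = out_dir, seed = seed)
  if (!is.null(yaml)) {
    y <- yaml::read_yaml(yaml)
    for (nm in intersect(names(y), names(cfg))) cfg[[nm]] <- y[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

resolve_genome <- function(genome) {
  if (inherits(genome, "cin_genome")) return(genome)
  if (identical(genome, "hg19")) return(hg19_genome())
  read_genome_model(genome)
}

# deterministic per-stage child seeds from the one recorded seed
stage_seed <- function(seed, stage) {
  (seed * 1009L + match(stage, c("simulate", "segment", "cutoff", "tdroc"))) %% 2147483647L
}

#' Run the full CIN pipeline
#'
#' simulate/load -> control panel -> QC gates -> Z-score -> CBS -> CIN score,
#' arm Z -> cutoff/classify -> survival report. QC-failed samples are
#' excluded from every downstream stage and listed (with the excluding rule)
#' in the manifest. All stage outputs are plain CSV/TSV/SEG in `out_dir`;
#' reruns under the same seed are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return A `cin_manifest`: list of output paths, parameter echo, exclusion
#'   table and per-stage log; pass to [cin_report()].
#' @export
run_cin_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    inform(msg)
  }

  genome <- resolve_genome(config$genome)
  grid <- build_bin_grid(genome, config$bin_size)
  say("stage grid: %d bins on %d chromosomes", nrow(grid), nrow(genome))

  if (!is.null(config$simulate)) {
    sim <- simulate_cohort(config$simulate, grid,
                           seed = stage_seed(config$seed, "simulate"))
    controls <- sim$controls
    tumors <- sim$tumors
    meta <- sim$meta
    truth_path <- file.path(config$out_dir, "truth.csv")
    readr::write_csv(select(sim$truth, -"events"), truth_path)
    say("stage simulate: %d controls, %d tumors", config$simulate$n_controls,
        config$simulate$n_tumors)
  } else {
    if (is.null(config$coverage_tsv) || is.null(config$clinical_csv)) {
      abort("Provide simulate= or coverage_tsv= + clinical_csv=.")
    }
    cov <- read_coverage_table(config$coverage_tsv, grid)
    controls <- filter(cov, .data$sample %in% config$controls)
    tumors <- filter(cov, !.data$sample %in% config$controls)
    meta <- readr::read_csv(config$clinical_csv, show_col_types = FALSE)
    truth_path <- NULL
    say("stage load: %d controls, %d tumors",
        dplyr::n_distinct(controls$sample), dplyr::n_distinct(tumors$sample))
  }

  panel <- build_panel(controls, grid)
  say("stage panel: %d usable bins of %d", sum(panel$usable), nrow(panel))

  qc_mad <- mad_qc(tumors, panel, config$qc)
  qc_seq <- if (all(c("total_reads", "pct_q30", "pct_unique_map") %in% names(meta))) {
    seq_qc_gate(meta, config$qc)
  } else {
    tibble(sample = unique(tumors$sample), seq_pass = TRUE, seq_fail_reasons = "")
  }
  qc <- full_join(qc_mad, qc_seq, by = "sample") |>
    mutate(pass = .data$mad_pass & .data$seq_pass,
           verdict = ifelse(.data$pass, "pass", paste0(
             "fail:", ifelse(.data$mad_pass, "", "mad,"),
             .data$seq_fail_reasons)))
  qc_path <- file.path(config$out_dir, "qc.csv")
  readr::write_csv(qc, qc_path)
  excluded <- filter(qc, !.data$pass)
  for (k in seq_len(nrow(excluded))) {
    say("excluded from analysis: %s (%s)", excluded$sample[k],
        excluded$verdict[k])
  }
  keep <- qc$sample[qc$pass]
  if (length(keep) == 0) abort("stage qc: every sample excluded.")
  tumors <- filter(tumors, .data$sample %in% keep)

  z <- zscore_bins(tumors, panel)
  segs <- segment_genome(z, grid, alpha = config$alpha, n_perm = config$n_perm,
                         min_width = config$min_width,
                         merge_sd = config$merge_sd,
                         seed = stage_seed(config$seed, "segment"))
  seg_path <- file.path(config$out_dir, "segments.seg")
  write_segments_seg(segs, seg_path)
  say("stage segment: %d segments over %d samples", nrow(segs),
      dplyr::n_distinct(segs$sample))

  segz <- segment_z(z, segs)
  scores <- cin_score(segz, z_min = config$z_min, use_abs = config$use_abs,
                      units = config$units)
  arms <- arm_z(z) |>
    pivot_wider(id_cols = "sample", names_from = "arm", values_from = "arm_z")

  clin <- meta |>
    filter(.data$sample %in% keep) |>
    inner_join(scores, by = "sample")
  if (is.numeric(config$cutoff)) {
    cutoff <- config$cutoff
    cut_fit <- NULL
    say("stage cutoff: fixed at %.3f", cutoff)
  } else {
    set.seed(stage_seed(config$seed, "cutoff"))
    cut_fit <- max_sel_rank_cutoff(clin$cin_score, clin$rfs_months,
                                   clin$relapse)
    cutoff <- cut_fit$cutoff
    say("stage cutoff: derived %.3f (max |S| %.2f, approx p %.3g)",
        cutoff, cut_fit$max_statistic, cut_fit$approx_p)
  }
  scores$cin_class <- classify_cin(scores$cin_score, cutoff)
  score_tbl <- scores |>
    left_join(arms, by = "sample") |>
    left_join(select(qc, "sample", "verdict"), by = "sample")
  score_path <- file.path(config$out_dir, "scores.csv")
  readr::write_csv(score_tbl, score_path)

  clin$cin_class <- classify_cin(clin$cin_score, cutoff)
  surv_data <- tibble(time = clin$rfs_months, event = clin$relapse,
                      cin_high = as.integer(clin$cin_class == "high"))
  km <- km_estimate(surv_data, clin$cin_class)
  lr <- logrank_test(surv_data, clin$cin_class)
  cox <- tryCatch(cox_fit(surv_data, "cin_high"), error = function(e) NULL)
  horizons <- 12 * seq_len(max(1, floor(max(surv_data$time) / 12)))
  tdroc <- td_roc(clin$cin_score, surv_data, horizons, n_boot = 200,
                  seed = stage_seed(config$seed, "tdroc"))
  km_path <- file.path(config$out_dir, "km.csv")
  readr::write_csv(km$curve, km_path)
  cox_path <- file.path(config$out_dir, "cox.csv")
  readr::write_csv(if (is.null(cox)) tibble() else tidy(cox), cox_path)
  tdroc_path <- file.path(config$out_dir, "tdroc.csv")
  readr::write_csv(tdroc, tdroc_path)
  clin_path <- file.path(config$out_dir, "clinical_scored.csv")
  readr::write_csv(clin, clin_path)
  say("stage survival: log-rank p %.4g; classes %d high / %d low", lr$p,
      sum(clin$cin_class == "high"), sum(clin$cin_class == "low"))

  manifest <- structure(list(
    paths = purrr::compact(list(
      qc = qc_path, segments = seg_path, scores = score_path,
      clinical = clin_path, km = km_path, cox = cox_path, tdroc = tdroc_path,
      truth = truth_path)),
    params = unclass(config)[setdiff(names(config), "simulate")],
    seed = config$seed, cutoff = cutoff, cutoff_fit = cut_fit,
    logrank = lr, km_median = km$median,
    excluded = select(excluded, "sample", "verdict"), log = log),
    class = "cin_manifest")
  manifest_path <- file.path(config$out_dir, "manifest.yaml")
  yaml::write_yaml(list(seed = config$seed, cutoff = cutoff,
                        paths = manifest$paths,
                        excluded = as.list(excluded$sample), log = log),
                   manifest_path)
  manifest$paths$manifest <- manifest_path
  manifest
}

#' Human-readable run summary
#'
#' Rebuilds the summary purely from the files recorded in the manifest:
#' class counts, KM medians, the Cox table, AUC(t), and CIN-by-covariate
#' association tables.
#'
#' @param manifest A `cin_manifest` from [run_cin_pipeline()].
#' @return Invisibly, a list of the summary tibbles.
#' @export
cin_report <- function(manifest) {
  stopifnot(inherits(manifest, "cin_manifest"))
  clin <- readr::read_csv(manifest$paths$clinical, show_col_types = FALSE)
  cox <- tryCatch(readr::read_csv(manifest$paths$cox, show_col_types = FALSE),
                  error = function(e) tibble())
  tdroc <- readr::read_csv(manifest$paths$tdroc, show_col_types = FALSE)
  km <- readr::read_csv(manifest$paths$km, show_col_types = FALSE)

  classes <- count(clin, .data$cin_class)
  covars <- intersect(c("sex", "smoking", "tumor_count", "grade", "stage"),
                      names(clin))
  assoc <- purrr::map(covars, function(v) {
    tab <- table(clin[[v]], clin$cin_class)
    p <- if (all(dim(tab) == c(2, 2)) && all(tab > 0)) {
      pearson_chi2(tab)$p
    } else NA_real_
    tibble(variable = v, p = p)
  }) |> purrr::list_rbind()

  med <- km |>
    group_by(.data$group) |>
    summarise(median = if (any(.data$surv <= 0.5)) {
      min(.data$time[.data$surv <= 0.5])
    } else NA_real_, .groups = "drop")

  cat("CIN pipeline run summary\n")
  cat(sprintf("  cutoff: %.3f\n", manifest$cutoff))
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", classes$cin_class, classes$n),
                    collapse = ", ")))
  cat(sprintf("  median RFS: %s\n",
              paste(sprintf("%s=%s", med$group,
                            ifelse(is.na(med$median), "not reached",
                                   sprintf("%.1f", med$median))),
                    collapse = ", ")))
  if (nrow(cox) > 0) {
    cat(sprintf("  Cox HR (high vs low): %.2f (%.2f-%.2f), p=%.4g\n",
                cox$hr[1], cox$hr_low[1], cox$hr_high[1], cox$p[1]))
  }
  cat("  AUC(t):\n")
  for (k in seq_len(nrow(tdroc))) {
    cat(sprintf("    %3.0f mo: %.3f\n", tdroc$horizon[k], tdroc$auc[k]))
  }
  if (nrow(assoc) > 0) {
    cat("  CIN-class associations (chi-square p):\n")
    for (k in seq_len(nrow(assoc))) {
      cat(sprintf("    %-12s %s\n", assoc$variable[k],
                  ifelse(is.na(assoc$p[k]), "-", sprintf("%.3f", assoc$p[k]))))
    }
  }
  invisible(list(classes = classes, km_median = med, cox = cox,
                 tdroc = tdroc, associations = assoc))
}
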