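#' Specification of a synthetic LC-WGS cohort
#'
#' Bundles every knob of the generator. The defaults emulate the study design
#' the package targets: an 11-donor healthy control panel and 50 tumors at
#' roughly 0.5x coverage in 200-kb bins (~700 reads per bin for ~10M reads
#' over the autosomes), FFPE-like negative-binomial counting noise, a shared
#' lognormal per-bin capture bias that control normalization must remove, a
#' menu of arm-level gains/losses, and an exponential recurrence model in
#' which the high-burden class carries a hazard ratio of 5.
#'
#' @param n_controls,n_tumors Panel and cohort sizes.
#' @param depth_mean Expected reads per bin for a copy-neutral bin.
#' @param bin_bias_sd Lognormal sd of the per-bin capture bias shared by all
#'   samples (0 disables bias).
#' @param noise_model `"negbin"`, `"poisson"`, or `"none"` (noiseless limit).
#' @param dispersion Negative-binomial dispersion (variance = mu + dispersion
#'   * mu^2); ignored for other noise models.
#' @param cna_menu List of menu entries, each `list(name=, events=, prob=)`
#'   where `events` is a tibble `chrom, start, end, copy_ratio`. Probabilities
#'   must sum to at most 1; the remainder is CNA-free. `NULL` uses
#'   [default_cna_menu()] for the genome backing `grid` at simulation time.
#' @param burden_threshold Implanted burden (sum of |log2 copy ratio| x length
#'   in Mb) above which a tumor's latent class is "high".
#' @param baseline_rate Exponential recurrence hazard (events/month) of the
#'   low-burden class.
#' @param log_hr_high Log hazard ratio of the high-burden class.
#' @param censor_time Administrative censoring time (months).
#' @return A list with class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 11, n_tumors = 50,
                        depth_mean = 700, bin_bias_sd = 0.1,
                        noise_model = c("negbin", "poisson", "none"),
                        dispersion = 0.1,
                        cna_menu = NULL, burden_threshold = 40,
                        baseline_rate = 0.003, log_hr_high = log(5),
                        censor_time = 84) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_controls >= 2, n_tumors >= 1, depth_mean > 0,
            bin_bias_sd >= 0, dispersion >= 0, baseline_rate > 0,
            censor_time > 0)
  if (!is.null(cna_menu)) {
    p <- sum(purrr::map_dbl(cna_menu, "prob"))
    if (p > 1 + 1e-9) abort("cna_menu probabilities must sum to <= 1.")
  }
  structure(list(
    n_controls = n_controls, n_tumors = n_tumors, depth_mean = depth_mean,
    bin_bias_sd = bin_bias_sd, noise_model = noise_model,
    dispersion = dispersion, cna_menu = cna_menu,
    burden_threshold = burden_threshold, baseline_rate = baseline_rate,
    log_hr_high = log_hr_high, censor_time = censor_time
  ), class = "cohort_spec")
}

#' Whole-arm copy-number event
#'
#' @param genome A `cin_genome` tibble.
#' @param arm Arm label such as `"chr8q"`.
#' @param copy_ratio Multiplicative coverage factor (1.5 = single-copy gain at
#'   purity 1, 0.5 = single-copy loss).
#' @return One-row event tibble.
#' @export
arm_event <- function(genome, arm, copy_ratio) {
  chrom <- sub("[pq]$", "", arm)
  side <- stringr::str_sub(arm, -1)
  row <- genome[genome$chrom == chrom, ]
  if (nrow(row) != 1) abort(sprintf("Unknown chromosome in arm '%s'.", arm))
  if (side == "p") {
    tibble(chrom = chrom, start = 0, end = row$cen_start, copy_ratio = copy_ratio)
  } else {
    tibble(chrom = chrom, start = row$cen_end, end = row$length,
           copy_ratio = copy_ratio)
  }
}

#' Default menu of tumor copy-number profiles
#'
#' Heavy profiles combine the arm-level gains (8q+, 16p+, 19q+, 20q+) and
#' losses (chr9, 17p, 11p) recurrent in urothelial tumors; light profiles
#' carry at most one modest event. Menu frequencies put ~70% of tumors in the
#' high-burden class.
#'
#' For genomes without those chromosome names (toy genomes), an equivalent
#' generic menu is built over the arms the genome does have.
#'
#' @param genome A `cin_genome` tibble.
#' @return List of menu entries for [cohort_spec()].
#' @export
default_cna_menu <- function(genome) {
  pick <- function(arms_ratios) {
    purrr::map(arms_ratios, ~ arm_event(genome, .x[[1]], as.numeric(.x[[2]]))) |>
      purrr::list_rbind() |>
      distinct(.data$chrom, .data$start, .data$end, .keep_all = TRUE)
  }
  canonical <- c("chr8", "chr9", "chr11", "chr16", "chr17", "chr19", "chr20")
  if (all(canonical %in% genome$chrom)) {
    return(list(
      list(name = "heavy_gain_loss",
           events = pick(list(list("chr8q", 1.5), list("chr16p", 1.5),
                              list("chr19q", 1.5), list("chr9p", 0.5),
                              list("chr9q", 0.5), list("chr17p", 0.5))),
           prob = 0.30),
      list(name = "heavy_gain",
           events = pick(list(list("chr8q", 1.5), list("chr20q", 1.5),
                              list("chr16p", 1.5), list("chr11p", 0.5))),
           prob = 0.25),
      list(name = "heavy_loss",
           events = pick(list(list("chr9p", 0.5), list("chr9q", 0.5),
                              list("chr17p", 0.5), list("chr19q", 1.5))),
           prob = 0.15),
      list(name = "light_single",
           events = pick(list(list("chr8q", 1.25))),
           prob = 0.15)
      # remaining probability: copy-neutral tumors
    ))
  }
  # generic fallback over available arms, same shape as the canonical menu
  ch <- genome$chrom
  w <- function(i) ch[(i - 1) %% length(ch) + 1]  # wrap chromosome index
  list(
    list(name = "heavy_gain_loss",
         events = pick(list(list(paste0(w(1), "q"), 1.5),
                            list(paste0(w(2), "q"), 1.5),
                            list(paste0(w(3), "p"), 0.5),
                            list(paste0(w(3), "q"), 0.5))),
         prob = 0.30),
    list(name = "heavy_gain",
         events = pick(list(list(paste0(w(1), "q"), 1.5),
                            list(paste0(w(2), "p"), 1.5),
                            list(paste0(w(4), "q"), 1.5))),
         prob = 0.25),
    list(name = "heavy_loss",
         events = pick(list(list(paste0(w(1), "p"), 0.5),
                            list(paste0(w(2), "q"), 0.5),
                            list(paste0(w(4), "p"), 0.5))),
         prob = 0.15),
    list(name = "light_single",
         events = pick(list(list(paste0(w(1), "q"), 1.25))),
         prob = 0.15)
  )
}

#' Shared per-bin capture bias
#'
#' Lognormal with unit mean, drawn once per cohort and shared across samples;
#' this correlated structure is exactly what control-panel normalization is
#' meant to remove.
#'
#' @param spec A [cohort_spec()].
#' @param grid Bin grid.
#' @param seed Optional integer seed.
#' @return Numeric vector, one bias factor per bin.
#' @export
simulate_bias <- function(spec, grid, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (spec$bin_bias_sd == 0) return(rep(1, nrow(grid)))
  rlnorm(nrow(grid), meanlog = -spec$bin_bias_sd^2 / 2, sdlog = spec$bin_bias_sd)
}

draw_counts <- function(mu, spec) {
  switch(spec$noise_model,
    none = mu,
    poisson = as.numeric(rpois(length(mu), mu)),
    negbin = if (spec$dispersion <= 0) {
      as.numeric(rpois(length(mu), mu))
    } else {
      as.numeric(rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion))
    })
}

profile_tbl <- function(sample, grid, values) {
  tibble(sample = sample, bin = grid$bin, chrom = grid$chrom,
         start = grid$start, end = grid$end, coverage = values)
}

#' Simulate a healthy-control panel
#'
#' @inheritParams simulate_bias
#' @param bias Optional pre-drawn bias vector (so tumors can share it); drawn
#'   from the stream when `NULL`.
#' @return Long coverage tibble of `spec$n_controls` samples; the bias used is
#'   attached as attribute `bias`.
#' @export
simulate_panel <- function(spec, grid, seed = NULL, bias = NULL) {
  if (spec$n_controls < 2) abort("Need at least 2 controls.")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(bias)) bias <- simulate_bias(spec, grid)
  mu <- spec$depth_mean * bias
  out <- purrr::map(seq_len(spec$n_controls), function(s) {
    profile_tbl(sprintf("control_%02d", s), grid, draw_counts(mu, spec))
  }) |> purrr::list_rbind()
  attr(out, "bias") <- bias
  out
}

# Per-bin expected copy ratio given events: length-weighted mixture for bins
# straddling an event boundary.
bin_copy_ratio <- function(events, grid) {
  ratio <- rep(1, nrow(grid))
  if (is.null(events) || nrow(events) == 0) return(ratio)
  ev_check_overlap(events)
  for (k in seq_len(nrow(events))) {
    sel <- grid$chrom == events$chrom[k] &
      grid$start < events$end[k] & grid$end > events$start[k]
    if (!any(sel)) next
    ov <- pmin(grid$end[sel], events$end[k]) - pmax(grid$start[sel], events$start[k])
    w <- ov / (grid$end[sel] - grid$start[sel])
    ratio[sel] <- ratio[sel] + w * (events$copy_ratio[k] - 1)
  }
  ratio
}

ev_check_overlap <- function(events) {
  if (any(events$copy_ratio <= 0)) abort("copy_ratio must be positive.")
  by_chr <- split(events, events$chrom)
  for (e in by_chr) {
    e <- e[order(e$start), ]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
      abort("Overlapping CNA events for one sample.")
    }
  }
  invisible(events)
}

#' Simulate one tumor coverage profile with implanted CNAs
#'
#' @param events Event tibble `chrom, start, end, copy_ratio` (non-overlapping).
#' @inheritParams simulate_panel
#' @param sample Sample id.
#' @return Coverage tibble for one sample.
#' @export
simulate_tumor <- function(events, spec, grid, seed = NULL, bias = NULL,
                           sample = "tumor") {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(bias)) bias <- simulate_bias(spec, grid)
  mu <- spec$depth_mean * bias * bin_copy_ratio(events, grid)
  profile_tbl(sample, grid, draw_counts(mu, spec))
}

#' Implanted copy-number burden of an event set
#'
#' Sum over events of |log2 copy ratio| times event length in Mb; this defines
#' the latent high/low class independently of the pipeline's own CIN cutoff,
#' so classification accuracy is measurable.
#'
#' @param events Event tibble (possibly empty or `NULL`).
#' @return Scalar burden.
#' @export
implanted_burden <- function(events) {
  if (is.null(events) || nrow(events) == 0) return(0)
  sum(abs(log2(events$copy_ratio)) * (events$end - events$start) / 1e6)
}

#' Simulate a full cohort: control panel, tumors, clinical table, truth
#'
#' Each tumor draws a profile from the CNA menu; its latent class is set by
#' implanted burden; recurrence-free survival comes from an exponential
#' proportional-hazards model with the spec's baseline rate and high-class log
#' hazard ratio, administratively censored. Clinical covariates are drawn to
#' match typical NMIBC cohort margins (mean age ~68, ~82% male, ~half
#' multifocal/high-grade/T1).
#'
#' @inheritParams simulate_panel
#' @return List with `controls` and `tumors` (long coverage tibbles), `meta`
#'   (clinical + sequencing-QC table), `truth` (per-tumor menu entry, burden,
#'   latent class, true event list), and `bias`.
#' @export
simulate_cohort <- function(spec, grid, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome <- grid_genome(grid)
  menu <- spec$cna_menu %||% default_cna_menu(genome)
  probs <- purrr::map_dbl(menu, "prob")
  menu <- c(menu, list(list(name = "neutral", events = NULL, prob = 1 - sum(probs))))
  bias <- simulate_bias(spec, grid)
  controls <- simulate_panel(spec, grid, bias = bias)

  idx <- sample.int(length(menu), spec$n_tumors, replace = TRUE,
                    prob = purrr::map_dbl(menu, "prob"))
  ids <- sprintf("tumor_%02d", seq_len(spec$n_tumors))
  tumors <- purrr::map(seq_len(spec$n_tumors), function(s) {
    simulate_tumor(menu[[idx[s]]]$events, spec, grid, bias = bias,
                   sample = ids[s])
  }) |> purrr::list_rbind()

  burden <- purrr::map_dbl(idx, ~ implanted_burden(menu[[.x]]$events))
  latent <- ifelse(burden > spec$burden_threshold, "high", "low")
  rate <- spec$baseline_rate * exp(spec$log_hr_high * (latent == "high"))
  t_event <- rexp(spec$n_tumors, rate)
  relapse <- as.integer(t_event <= spec$censor_time)
  rfs <- pmin(t_event, spec$censor_time)
  if (all(relapse == 0)) warn("Degenerate hazard: every subject censored.")

  n <- spec$n_tumors
  meta <- tibble(
    sample = ids, role = "tumor",
    total_reads = round(pmax(rnorm(n, 1.2e7, 1e6), 5e6)),
    pct_q30 = pmin(99, pmax(80, rnorm(n, 92, 2))),
    pct_unique_map = pmin(99, pmax(65, rnorm(n, 80, 3))),
    age = round(pmin(95, pmax(30, rnorm(n, 68, 11)))),
    sex = ifelse(runif(n) < 0.82, "male", "female"),
    smoking = ifelse(runif(n) < 0.22, "yes", "no"),
    tumor_size = round(pmax(0.5, rnorm(n, 2.8, 1.2)), 1),
    tumor_count = ifelse(runif(n) < 0.5, "multiple", "single"),
    grade = ifelse(runif(n) < 0.52, "high", "low"),
    stage = ifelse(runif(n) < 0.58, "T1", "Ta"),
    intravesical_drug = sample(
      c("BCG", "gemcitabine", "hydroxycamptothecin", "mitomycin", "pirarubicin"),
      n, replace = TRUE, prob = c(0.16, 0.62, 0.06, 0.12, 0.04)),
    relapse = relapse,
    rfs_months = rfs)
  menu_names <- purrr::map_chr(idx, ~ menu[[.x]]$name)
  event_sets <- purrr::map(idx, ~ menu[[.x]]$events %||% tibble(
    chrom = character(), start = numeric(), end = numeric(),
    copy_ratio = numeric()))
  truth <- tibble(
    sample = ids,
    menu = menu_names,
    burden = burden, latent_class = latent,
    true_hr = exp(spec$log_hr_high),
    events = event_sets)
  list(controls = controls, tumors = tumors, meta = meta, truth = truth,
       bias = bias)
}

# Recover the genome table backing a grid (lengths and centromere bounds come
# from the tiling itself).
grid_genome <- function(grid) {
  g <- grid |>
    group_by(.data$chrom) |>
    summarise(
      length = max(.data$end),
      cen_start = if (any(.data$centromeric)) min(.data$start[.data$centromeric]) + 1 else NA_real_,
      cen_end = if (any(.data$centromeric)) max(.data$end[.data$centromeric]) - 1 else NA_real_,
      .groups = "drop")
  # fall back to the p/q boundary when no bin is flagged
  pq <- grid |>
    group_by(.data$chrom) |>
    summarise(pmax_end = suppressWarnings(max(.data$end[.data$arm %in% "p"])),
              qmin_start = suppressWarnings(min(.data$start[.data$arm %in% "q"])),
              .groups = "drop")
  g <- left_join(g, pq, by = "chrom") |>
    mutate(cen_start = dplyr::coalesce(.data$cen_start, .data$pmax_end),
           cen_end = dplyr::coalesce(.data$cen_end, .data$qmin_start)) |>
    select("chrom", "length", "cen_start", "cen_end")
  g <- g[match(unique(grid$chrom), g$chrom), ]
  validate_genome(g)
}
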