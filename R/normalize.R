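#' Build a control panel from healthy-control coverage profiles
#'
#' Per-bin arithmetic mean and sample standard deviation (denominator n-1)
#' across controls. Bins with zero variance, zero mean, or a centromeric flag
#' are marked unusable and masked from all downstream Z-scores, segmentation
#' and scoring.
#'
#' @param controls Long coverage tibble of >= 2 control samples.
#' @param grid Bin grid the controls were counted on.
#' @return Tibble `bin, chrom, start, end, arm, mean_raw, sd_raw, usable` with
#'   class `cin_panel`; the per-sample control matrix is retained in attribute
#'   `control_matrix` for leave-one-out work.
#' @export
build_panel <- function(controls, grid) {
  m <- coverage_matrix(controls, grid)
  if (ncol(m) < 2) abort("Need at least 2 control samples.")
  mean_raw <- unname(rowMeans(m))
  sd_raw <- unname(apply(m, 1, sd))
  panel <- tibble(
    bin = grid$bin, chrom = grid$chrom, start = grid$start, end = grid$end,
    arm = grid$arm, mean_raw = mean_raw, sd_raw = sd_raw,
    usable = !grid$centromeric & sd_raw > 0 & mean_raw > 0)
  attr(panel, "control_matrix") <- m
  attr(panel, "n_controls") <- ncol(m)
  class(panel) <- c("cin_panel", class(panel))
  panel
}

# bins x samples matrix from a long coverage tibble, validated against grid
coverage_matrix <- function(coverage, grid) {
  samples <- unique(coverage$sample)
  wide <- coverage |>
    select("sample", "bin", "coverage") |>
    pivot_wider(names_from = "sample", values_from = "coverage")
  if (nrow(wide) != nrow(grid) || !setequal(wide$bin, grid$bin)) {
    abort("Coverage profiles do not cover the grid exactly (grid mismatch).")
  }
  wide <- wide[match(grid$bin, wide$bin), ]
  m <- as.matrix(wide[, samples, drop = FALSE])
  if (anyNA(m)) abort("Missing (sample, bin) coverage values.")
  rownames(m) <- grid$bin
  m
}

#' Per-bin Z-scores against a control panel
#'
#' The normalization at the heart of the pipeline:
#' `z = (coverage_raw - mean(controls)) / sd(controls)` per bin, computed only
#' over usable bins; masked bins carry `NA`.
#'
#' @param coverage Long coverage tibble (one or more samples).
#' @param panel A [build_panel()] result.
#' @return Long tibble `sample, bin, chrom, start, end, arm, z, usable`.
#' @export
zscore_bins <- function(coverage, panel) {
  out <- coverage |>
    inner_join(select(panel, "bin", "arm", "mean_raw", "sd_raw", "usable"),
               by = "bin") |>
    mutate(z = ifelse(.data$usable,
                      (.data$coverage - .data$mean_raw) / .data$sd_raw,
                      NA_real_)) |>
    select("sample", "bin", "chrom", "start", "end", "arm", "z", "usable")
  if (nrow(out) != nrow(coverage)) abort("Coverage bins not aligned with panel.")
  out
}

#' QC thresholds
#'
#' @param mad_threshold Maximum allowed MAD of per-bin log2 copy ratios
#'   (raw/unscaled MAD; samples strictly exceeding it fail).
#' @param min_reads,min_pct_q30,min_pct_unique Sequencing-metadata gates.
#' @return List with class `qc_config`.
#' @export
qc_config <- function(mad_threshold = 0.38, min_reads = 1e7,
                      min_pct_q30 = 85, min_pct_unique = 70) {
  stopifnot(mad_threshold > 0, min_reads > 0, min_pct_q30 > 0, min_pct_unique > 0)
  structure(list(mad_threshold = mad_threshold, min_reads = min_reads,
                 min_pct_q30 = min_pct_q30, min_pct_unique = min_pct_unique),
            class = "qc_config")
}

#' Noise QC: MAD of the genomic log copy ratio
#'
#' Per sample, the log ratio `log2(coverage / panel mean)` is computed over
#' usable bins (pseudocount 0.5 added to zero coverages), and its
#' `MAD = median(|ratio - median(ratio)|)` without
#' the 1.4826 consistency factor: the conventional 0.38 threshold operates on
#' the raw MAD. A sample fails iff its MAD strictly exceeds the threshold.
#'
#' @param coverage Long coverage tibble.
#' @param panel Control panel.
#' @param cfg A [qc_config()].
#' @return Tibble `sample, mad, mad_pass`.
#' @export
mad_qc <- function(coverage, panel, cfg = qc_config()) {
  usable <- panel$bin[panel$usable]
  if (length(usable) == 0) abort("No usable bins for MAD QC.")
  coverage |>
    filter(.data$bin %in% usable) |>
    inner_join(select(panel, "bin", "mean_raw"), by = "bin") |>
    group_by(.data$sample) |>
    summarise(
      mad = {
        r <- log2(ifelse(.data$coverage > 0, .data$coverage, 0.5) / .data$mean_raw)
        median(abs(r - median(r)))
      },
      .groups = "drop") |>
    mutate(mad_pass = .data$mad <= cfg$mad_threshold + 1e-9)  # strict "exceeds" up to fp noise
}

#' Sequencing-metadata QC gate
#'
#' @param meta Tibble with `sample, total_reads, pct_q30, pct_unique_map`.
#' @param cfg A [qc_config()].
#' @return Tibble `sample, seq_pass, seq_fail_reasons` (comma-separated list
#'   of every violated criterion, empty when passing).
#' @export
seq_qc_gate <- function(meta, cfg = qc_config()) {
  meta |>
    mutate(
      seq_fail_reasons = purrr::pmap_chr(
        list(.data$total_reads, .data$pct_q30, .data$pct_unique_map),
        function(reads, q30, uniq) {
          reasons <- c(
            if (reads < cfg$min_reads) "reads",
            if (q30 < cfg$min_pct_q30) "q30",
            if (uniq < cfg$min_pct_unique) "unique_map")
          paste(reasons, collapse = ",")
        }),
      seq_pass = .data$seq_fail_reasons == "") |>
    select("sample", "seq_pass", "seq_fail_reasons")
}
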