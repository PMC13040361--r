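#' Segment-level Z summaries
#'
#' For every segment: its genomic length `L` in megabases and `z_seg`, the
#' unweighted mean of usable bin Z-scores inside it.
#'
#' @param zprofile Long Z tibble from [zscore_bins()].
#' @param segments Segment tibble from [segment_genome()] for the same
#'   sample(s).
#' @return `segments` with columns `L` (Mb) and `z_seg` appended.
#' @export
segment_z <- function(zprofile, segments) {
  if (nrow(segments) == 0) abort("Empty segment set.")
  z <- zprofile |> filter(.data$usable)
  segments |>
    mutate(L = (.data$end - .data$start) / 1e6,
           z_seg = purrr::pmap_dbl(
             list(.data$sample, .data$start_bin, .data$end_bin),
             function(s, b0, b1) {
               mean(z$z[z$sample == s & z$bin >= b0 & z$bin <= b1])
             }))
}

#' Genome-wide chromosomal instability score
#'
#' `CIN = sum over segments of L x |z_seg|`, restricted to segments whose
#' |z_seg| reaches `z_min`. `L` is in megabases by default, which puts scores
#' on the scale of cohort cutoffs in the thousands for genomes carrying
#' arm-level events of |Z| 3-10. The absolute value keeps gains and losses
#' from cancelling; set `use_abs = FALSE` for the signed sum and `z_min = 0`
#' for the unfiltered one.
#'
#' @param segz Output of [segment_z()].
#' @param z_min Minimum |z_seg| for a segment to contribute (default 2).
#' @param use_abs Sum |z_seg| (default) or signed z_seg.
#' @param units `"Mb"`, `"bp"` or `"bins"` for the length factor.
#' @return Tibble `sample, cin_score`.
#' @export
cin_score <- function(segz, z_min = 2, use_abs = TRUE, units = c("Mb", "bp", "bins")) {
  units <- match.arg(units)
  segz |>
    mutate(len = switch(units, Mb = .data$L, bp = .data$L * 1e6,
                        bins = as.numeric(.data$n_bins)),
           zc = if (use_abs) abs(.data$z_seg) else .data$z_seg) |>
    group_by(.data$sample) |>
    summarise(cin_score = sum(.data$len[abs(.data$z_seg) >= z_min] *
                                .data$zc[abs(.data$z_seg) >= z_min]),
              .groups = "drop")
}

#' Chromosome-arm Z-scores
#'
#' Mean usable-bin Z per chromosome arm (bins are equal width, so this is the
#' length-weighted arm mean up to the remainder bin). Arms with no usable bins
#' are absent.
#'
#' @param zprofile Long Z tibble.
#' @return Tibble `sample, arm` (label such as `"chr8q"`) `, arm_z, n_bins`.
#' @export
arm_z <- function(zprofile) {
  zprofile |>
    filter(.data$usable, !is.na(.data$arm)) |>
    mutate(arm = paste0(.data$chrom, .data$arm)) |>
    group_by(.data$sample, .data$arm) |>
    summarise(arm_z = mean(.data$z), n_bins = dplyr::n(), .groups = "drop")
}

#' Arm positivity call
#'
#' An arm is called positive when its Z-score reaches the cutoff (boundary
#' inclusive: `arm_z >= cutoff`).
#'
#' @param arm_z_value Numeric vector of arm Z-scores.
#' @param cutoff Arm-specific cutoff (e.g. an ROC-derived one).
#' @return Logical vector.
#' @export
arm_positive <- function(arm_z_value, cutoff) {
  stopifnot(all(is.finite(arm_z_value)), is.finite(cutoff))
  arm_z_value >= cutoff
}

#' CIN class from a score and cutoff
#'
#' High iff the score is strictly above the cutoff ("above the threshold" =
#' high), low otherwise.
#'
#' @param score Numeric vector of CIN scores.
#' @param cutoff Scalar cutoff.
#' @return Character vector `"high"`/`"low"`.
#' @export
classify_cin <- function(score, cutoff) {
  stopifnot(all(is.finite(score)), is.finite(cutoff))
  ifelse(score > cutoff, "high", "low")
}

#' Optimal survival cutoff by maximally selected rank statistics
#'
#' Scans every admissible cutpoint (midpoints between consecutive ordered
#' unique scores whose induced group proportions lie within `[eps, 1 - eps]`),
#' computes the standardized two-group log-rank statistic under the
#' conditional permutation distribution of log-rank scores, and returns the
#' cutpoint with the maximal |statistic| (ties break toward the smaller
#' cutpoint). The selection-adjusted p-value uses the Lausen-Schumacher
#' improved Bonferroni bound over the candidate set.
#'
#' @param scores Numeric marker (e.g. CIN scores).
#' @param times Follow-up times (months, > 0).
#' @param events Event indicators (1 relapse / 0 censored).
#' @param eps Minimum group proportion for a candidate cutpoint, in (0, 0.5).
#' @return `maxstat_cutoff` object: list with `cutoff`, `max_statistic`,
#'   `approx_p`, `candidates` (tibble cutpoint/statistic/n_low), `n`.
#' @export
max_sel_rank_cutoff <- function(scores, times, events, eps = 0.1) {
  stopifnot(length(scores) == length(times), length(times) == length(events),
            eps > 0, eps < 0.5)
  n <- length(scores)
  if (n < 10) abort("Need at least 10 samples for cutoff selection.")
  if (!any(events == 1) || !any(events == 0)) {
    abort("Need both events and censored observations.")
  }
  a <- logrank_scores(times, events)
  abar <- mean(a)
  ss <- sum((a - abar)^2)

  uq <- sort(unique(scores))
  if (length(uq) < 2) abort("No admissible candidate cutpoints.")
  cand <- (uq[-length(uq)] + uq[-1]) / 2
  stats <- purrr::map_dbl(cand, function(cut) {
    low <- scores <= cut
    m <- sum(low)
    if (m / n < eps || m / n > 1 - eps) return(NA_real_)
    S <- sum(a[low])
    v <- m * (n - m) / (n * (n - 1)) * ss
    if (v <= 0) return(NA_real_)
    abs(S - m * abar) / sqrt(v)
  })
  keep <- !is.na(stats)
  if (!any(keep)) abort("No admissible candidate cutpoints.")
  cand <- cand[keep]
  stats <- stats[keep]
  best <- which.max(stats)  # first max = smaller cutpoint on ties
  m_sizes <- purrr::map_int(cand, ~ sum(scores <= .x))
  out <- structure(list(
    cutoff = cand[best],
    max_statistic = stats[best],
    approx_p = p_lausen_improved(stats[best], n, m_sizes),
    candidates = tibble(cutpoint = cand, statistic = stats, n_low = m_sizes),
    n = n), class = "maxstat_cutoff")
  out
}

# Log-rank (Savage) scores: a_i = event_i - Nelson-Aalen cumulative hazard at
# the subject's observed time.
logrank_scores <- function(times, events) {
  n <- length(times)
  ord <- order(times)
  t_s <- times[ord]
  e_s <- events[ord]
  at_risk <- n - seq_len(n) + 1
  # cumulative hazard evaluated at each sorted observation, ties share a value
  dt <- unique(t_s[e_s == 1])
  haz <- vapply(t_s, function(tt) {
    sum(vapply(dt[dt <= tt], function(u) {
      sum(e_s == 1 & t_s == u) / sum(t_s >= u)
    }, numeric(1)))
  }, numeric(1))
  a <- numeric(n)
  a[ord] <- e_s - haz
  a
}

# Improved Bonferroni bound (Lausen-Schumacher) for the maximally selected
# standardized statistic over ordered candidate group sizes m.
p_lausen_improved <- function(b, N, m) {
  m <- sort(unique(m))
  if (length(m) < 2) return(min(1, 2 * (1 - pnorm(b))))
  m1 <- m[-length(m)]
  m2 <- m[-1]
  t <- sqrt(1 - m1 * (N - m2) / ((N - m1) * m2))
  D <- sum(1 / pi * exp(-b^2 / 2) * (t - (b^2 / 4 - 1) * t^3 / 6))
  min(1, max(0, 2 * (1 - pnorm(b)) + D))
}

#' @export
print.maxstat_cutoff <- function(x, ...) {
  cat("Maximally selected rank statistic\n")
  cat(sprintf("  cutoff: %.4f   max |S|: %.3f   approx p: %.4g   n: %d\n",
              x$cutoff, x$max_statistic, x$approx_p, x$n))
  invisible(x)
}

#' @export
tidy.maxstat_cutoff <- function(x, ...) x$candidates

#' @export
glance.maxstat_cutoff <- function(x, ...) {
  tibble(cutoff = x$cutoff, max_statistic = x$max_statistic,
         approx_p = x$approx_p, n_candidates = nrow(x$candidates), n = x$n)
}

#' @export
autoplot.maxstat_cutoff <- function(object, ...) {
  ggplot2::ggplot(object$candidates,
                  ggplot2::aes(x = .data$cutpoint, y = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = 2) +
    ggplot2::labs(x = "candidate cutoff", y = "standardized log-rank |S|") +
    ggplot2::theme_minimal()
}

#' Per-segment relapse vs non-relapse comparison
#'
#' On a common segment grid (e.g. one sample's segments, or recurrent
#' segments), compares per-sample mean Z between two groups with a two-sided
#' Wilcoxon rank-sum test; reports the group mean difference and log10(p).
#' Segments with `log10(p) < -1.3` (p < 0.05) are flagged significant.
#'
#' @param seg_matrix Samples x segments numeric matrix (or data frame) of
#'   per-sample mean Z over each common segment.
#' @param group Logical or 0/1 vector, length nrow(seg_matrix); TRUE/1 =
#'   relapse.
#' @return Tibble `segment, mean_diff, log10_p, significant`.
#' @export
segment_group_test <- function(seg_matrix, group) {
  m <- as.matrix(seg_matrix)
  group <- as.logical(group)
  if (length(group) != nrow(m)) abort("group length must match rows.")
  if (sum(group) < 2 || sum(!group) < 2) abort("Need >= 2 samples per group.")
  segs <- colnames(m) %||% as.character(seq_len(ncol(m)))
  purrr::map(seq_len(ncol(m)), function(j) {
    x <- m[group, j]
    y <- m[!group, j]
    p <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = FALSE)$p.value)
    if (!is.finite(p)) p <- 1  # constant segment in both groups
    tibble(segment = segs[j], mean_diff = mean(x) - mean(y),
           log10_p = log10(p))
  }) |>
    purrr::list_rbind() |>
    mutate(significant = .data$log10_p < -1.3)
}
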