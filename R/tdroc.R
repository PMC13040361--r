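#' Time-dependent ROC with inverse-probability-of-censoring weights
#'
#' Cumulative/dynamic AUC(t): at each horizon, cases are subjects with an
#' observed event by t, controls those still event-free past t. Cases are
#' weighted by 1/G(T_i) where G is the Kaplan-Meier estimate of the censoring
#' distribution; with no censoring this reduces to empirical pair counting.
#' Percentile bootstrap confidence bands (resampling subjects).
#'
#' @param marker Numeric risk marker (higher = higher risk).
#' @param data Tibble with `time`, `event`.
#' @param horizons Evaluation times within the observed range.
#' @param n_boot Bootstrap resamples for the CI (0 disables).
#' @param conf_level CI level.
#' @param seed Optional seed for the bootstrap.
#' @return Tibble `horizon, auc, auc_low, auc_high, n_case, n_control`.
#' @export
td_roc <- function(marker, data, horizons, n_boot = 500, conf_level = 0.95,
                   seed = NULL) {
  stopifnot(length(marker) == nrow(data))
  if (any(horizons <= 0) || any(horizons > max(data$time))) {
    abort("Horizons must lie within the observed time range.")
  }
  if (!is.null(seed)) set.seed(seed)
  point <- purrr::map(horizons, ~ ipcw_auc_at(marker, data$time, data$event, .x)) |>
    purrr::list_rbind()
  if (n_boot > 0) {
    n <- nrow(data)
    boots <- purrr::map(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      purrr::map_dbl(horizons,
                     ~ ipcw_auc_at(marker[idx], data$time[idx],
                                   data$event[idx], .x)$auc)
    })
    bm <- do.call(rbind, boots)
    alpha <- (1 - conf_level) / 2
    point$auc_low <- apply(bm, 2, quantile, probs = alpha, na.rm = TRUE)
    point$auc_high <- apply(bm, 2, quantile, probs = 1 - alpha, na.rm = TRUE)
  } else {
    point$auc_low <- NA_real_
    point$auc_high <- NA_real_
  }
  point[, c("horizon", "auc", "auc_low", "auc_high", "n_case", "n_control")]
}

ipcw_auc_at <- function(marker, time, event, horizon) {
  is_case <- time <= horizon & event == 1
  is_ctrl <- time > horizon
  n_case <- sum(is_case); n_ctrl <- sum(is_ctrl)
  if (n_case == 0 || n_ctrl == 0) {
    return(tibble(horizon = horizon, auc = NA_real_,
                  n_case = n_case, n_control = n_ctrl))
  }
  G <- censoring_km(time, event)
  w <- 1 / pmax(G(time[is_case]), 1e-10)  # case weight 1/G(T_i)
  mc <- marker[is_case]; mk <- marker[is_ctrl]
  num <- 0
  for (i in seq_len(n_case)) {
    num <- num + w[i] * (sum(mc[i] > mk) + 0.5 * sum(mc[i] == mk))
  }
  tibble(horizon = horizon, auc = num / (sum(w) * n_ctrl),
         n_case = n_case, n_control = n_ctrl)
}

# KM of the censoring distribution, evaluated just before t (left limit), as a
# step function. With no censoring this is identically 1.
censoring_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  st <- c(0, fit$time)
  sv <- c(1, fit$surv)
  function(t) {
    idx <- findInterval(t - 1e-12, st)  # left-continuous evaluation
    sv[pmax(idx, 1)]
  }
}

#' KM curve plot for CIN classes (or any grouping)
#'
#' @param data Tibble with `time`, `event`.
#' @param group Grouping vector.
#' @return A ggplot.
#' @export
plot_km <- function(data, group) {
  km <- km_estimate(data, group)
  steps <- km$curve |>
    group_by(.data$group) |>
    group_modify(~ tibble(time = c(0, rep(.x$time, each = 2)),
                          surv = c(1, 1, rep(.x$surv, each = 2)[-(2 * nrow(.x))]))) |>
    ungroup()
  ggplot2::ggplot(steps, ggplot2::aes(.data$time, .data$surv,
                                      color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "recurrence-free survival",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' AUC(t) plot
#'
#' @param tdroc Output of [td_roc()].
#' @return A ggplot.
#' @export
plot_td_roc <- function(tdroc) {
  ggplot2::ggplot(tdroc, ggplot2::aes(.data$horizon, .data$auc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$auc_low,
                                      ymax = .data$auc_high), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::labs(x = "horizon (months)", y = "AUC(t)") +
    ggplot2::theme_minimal()
}

#' Z-profile plot with segment overlay
#'
#' @param zprofile Long Z tibble for one sample.
#' @param segments Optional matching segment tibble.
#' @return A ggplot.
#' @export
plot_z_profile <- function(zprofile, segments = NULL) {
  p <- ggplot2::ggplot(filter(zprofile, .data$usable),
                       ggplot2::aes(.data$bin, .data$z)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::facet_grid(~ .data$chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "bin", y = "Z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing = ggplot2::unit(0.1, "lines"),
                   axis.text.x = ggplot2::element_blank())
  if (!is.null(segments)) {
    p <- p + ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(x = .data$start_bin, xend = .data$end_bin,
                   y = .data$seg_mean, yend = .data$seg_mean),
      color = "red", linewidth = 0.8, inherit.aes = FALSE)
  }
  p
}
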