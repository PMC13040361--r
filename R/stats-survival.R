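#' Contingency-table tests
#'
#' `pearson_chi2()` is the uncorrected Pearson chi-square (df 1 for a 2x2
#' table) -- continuity correction is deliberately off, matching how
#' clinical baseline tables are conventionally reported. `fisher_exact()` is
#' the two-sided Fisher exact test summing hypergeometric probabilities no
#' larger than the observed table's.
#'
#' @param table 2x2 (or r x c) matrix of nonnegative integer counts.
#' @return Tibble `statistic, df, p` (chi-square) or `p` (Fisher).
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("Zero row or column margin.")
  }
  fit <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  tibble(statistic = unname(fit$statistic), df = unname(fit$parameter),
         p = fit$p.value)
}

#' @rdname pearson_chi2
#' @export
fisher_exact <- function(table) {
  fit <- stats::fisher.test(as.matrix(table))
  tibble(p = fit$p.value)
}

#' Two-group location tests
#'
#' `t_test2()` defaults to the pooled-variance two-sided t-test (Welch by
#' flag); `mann_whitney()` is the normal-approximation Mann-Whitney U with tie
#' correction and no continuity correction.
#'
#' @param x,y Numeric samples, n >= 2 each.
#' @param pooled Use pooled variance (default) or Welch.
#' @return Tibble of statistic and p.
#' @export
t_test2 <- function(x, y, pooled = TRUE) {
  fit <- stats::t.test(x, y, var.equal = pooled)
  tibble(t = unname(fit$statistic), df = unname(fit$parameter), p = fit$p.value)
}

#' @rdname t_test2
#' @export
mann_whitney <- function(x, y) {
  fit <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
  tibble(U = unname(fit$statistic), p = fit$p.value)
}

#' Kaplan-Meier estimate with the <= 0.5 median convention
#'
#' Product-limit estimator per group; the median is the first observed time at
#' which the survival estimate drops to 0.5 or below, and is `NA` ("not
#' reached") when the curve never does.
#'
#' @param data Tibble with columns `time` (> 0) and `event` (1/0).
#' @param group Optional grouping vector (defaults to one group).
#' @return List with `curve` (tibble `group, time, n_risk, n_event, surv`) and
#'   `median` (tibble `group, median`).
#' @export
km_estimate <- function(data, group = NULL) {
  group <- group %||% rep("all", nrow(data))
  fit <- survival::survfit(survival::Surv(data$time, data$event) ~ g,
                           data = data.frame(g = group))
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(unique(group), length(sm$time)) else {
    sub("^g=", "", as.character(sm$strata))
  }
  curve <- tibble(group = grp, time = sm$time, n_risk = sm$n.risk,
                  n_event = sm$n.event, surv = sm$surv)
  med <- curve |>
    group_by(.data$group) |>
    summarise(median = if (any(.data$surv <= 0.5)) {
      min(.data$time[.data$surv <= 0.5])
    } else NA_real_, .groups = "drop")
  list(curve = curve, median = med)
}

#' Two-group log-rank test
#'
#' @inheritParams km_estimate
#' @param group Grouping vector with two levels.
#' @return Tibble `statistic, df, p`.
#' @export
logrank_test <- function(data, group) {
  fit <- survival::survdiff(survival::Surv(data$time, data$event) ~ g,
                            data = data.frame(g = group))
  df <- length(fit$n) - 1
  tibble(statistic = fit$chisq, df = df,
         p = pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood Newton-Raphson via the survival package, Efron tie
#' handling by default; Wald 95% CIs as exp(coef +/- 1.96 se). Monotone
#' likelihood / non-convergence is surfaced as an error rather than silently
#' returned.
#'
#' @param data Tibble with `time`, `event` and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return `cin_coxfit` object wrapping the survival fit; `tidy()` gives the
#'   coefficient table (`term, coef, hr, hr_low, hr_high, se, z, p`),
#'   `glance()` the model-level log-likelihoods, n, and concordance.
#' @export
cox_fit <- function(data, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(data$event) < 1) abort("Need at least one event.")
  consts <- covariates[purrr::map_lgl(covariates, ~ length(unique(data[[.x]])) < 2)]
  if (length(consts) > 0) {
    abort(paste0("Constant covariate(s): ", paste(consts, collapse = ", ")))
  }
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(f, data = data, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations",
                conditionMessage(w))) {
        abort(paste("Cox fit did not converge:", conditionMessage(w)))
      }
      invokeRestart("muffleWarning")
    })
  if (any(!is.finite(stats::coef(fit))) ||
      any(sqrt(diag(fit$var)) > 1e3)) {
    abort("Cox fit did not converge (monotone likelihood?).")
  }
  structure(list(fit = fit, data = data, covariates = covariates, ties = ties),
            class = "cin_coxfit")
}

#' @export
tidy.cin_coxfit <- function(x, ...) {
  co <- stats::coef(x$fit)
  se <- sqrt(diag(x$fit$var))
  tibble(term = names(co), coef = unname(co), hr = exp(unname(co)),
         hr_low = exp(unname(co) - 1.96 * se),
         hr_high = exp(unname(co) + 1.96 * se),
         se = se, z = unname(co) / se,
         p = 2 * pnorm(-abs(unname(co) / se)))
}

#' @export
glance.cin_coxfit <- function(x, ...) {
  tibble(n = x$fit$n, n_events = x$fit$nevent,
         loglik_null = x$fit$loglik[1], loglik = x$fit$loglik[2],
         concordance = unname(x$fit$concordance["concordance"]))
}

#' @export
print.cin_coxfit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties): n=%d, events=%d\n",
              x$ties, x$fit$n, x$fit$nevent))
  print(tidy(x))
  invisible(x)
}

#' Proportional-hazards diagnostics (Schoenfeld residuals)
#'
#' Grambsch-Therneau score test of scaled Schoenfeld residuals against
#' KM-transformed time; per-covariate and global p-values.
#'
#' @param fit A [cox_fit()] object.
#' @return Tibble `term, chisq, df, p` including a `"GLOBAL"` row.
#' @export
ph_test <- function(fit) {
  z <- survival::cox.zph(fit$fit, transform = "km")
  tab <- as.data.frame(z$table)
  tibble(term = rownames(tab), chisq = tab$chisq, df = tab$df, p = tab$p)
}

#' Likelihood-ratio test between nested Cox models
#'
#' @param fit_full,fit_reduced [cox_fit()] objects on the same data, reduced
#'   covariates a subset of the full ones.
#' @return Tibble `chisq, df, p`.
#' @export
lrt_nested <- function(fit_full, fit_reduced) {
  if (!all(fit_reduced$covariates %in% fit_full$covariates)) {
    abort("Reduced covariates must be a subset of the full model's.")
  }
  if (fit_full$fit$n != fit_reduced$fit$n) abort("Models fit on different data.")
  df <- length(stats::coef(fit_full$fit)) - length(stats::coef(fit_reduced$fit))
  chisq <- 2 * (fit_full$fit$loglik[2] - fit_reduced$fit$loglik[2])
  tibble(chisq = chisq, df = df,
         p = if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else 1)
}

#' Harrell's concordance index
#'
#' Fraction of usable pairs (the earlier-time subject has an event) in which
#' the higher-risk marker belongs to the earlier event; marker ties count 0.5.
#' Computed by a direct pairwise scan.
#'
#' @param marker Numeric risk marker (higher = higher risk), or a
#'   [cox_fit()] whose linear predictor is used.
#' @param data Tibble with `time`, `event`.
#' @return Scalar concordance.
#' @export
c_index <- function(marker, data) {
  if (inherits(marker, "cin_coxfit")) {
    marker <- unname(stats::predict(marker$fit, type = "lp"))
  }
  stopifnot(length(marker) == nrow(data))
  t <- data$time; e <- data$event
  conc <- 0; n_pairs <- 0
  for (i in seq_along(t)) {
    if (e[i] != 1) next
    usable <- t > t[i] | (t == t[i] & e == 0)  # i is the earlier event
    n_pairs <- n_pairs + sum(usable)
    conc <- conc + sum(marker[i] > marker[usable]) +
      0.5 * sum(marker[i] == marker[usable])
  }
  if (n_pairs == 0) abort("No usable pairs.")
  conc / n_pairs
}

#' Net reclassification improvement
#'
#' Categorical NRI with user-supplied risk-category thresholds:
#' `[P(up|event) - P(down|event)] + [P(down|nonevent) - P(up|nonevent)]`.
#'
#' @param risk_old,risk_new Numeric predicted risks.
#' @param outcome 1/0 event indicator.
#' @param thresholds Cut points defining risk categories.
#' @return Tibble `nri_total, nri_event, nri_nonevent`.
#' @export
nri <- function(risk_old, risk_new, outcome, thresholds) {
  stopifnot(length(risk_old) == length(risk_new),
            length(risk_new) == length(outcome))
  cat_of <- function(r) findInterval(r, sort(thresholds))
  co <- cat_of(risk_old); cn <- cat_of(risk_new)
  ev <- outcome == 1
  if (!any(ev) || all(ev)) abort("Need both events and non-events.")
  up <- cn > co; down <- cn < co
  nri_event <- mean(up[ev]) - mean(down[ev])
  nri_nonevent <- mean(down[!ev]) - mean(up[!ev])
  tibble(nri_total = nri_event + nri_nonevent,
         nri_event = nri_event, nri_nonevent = nri_nonevent)
}

#' ROC AUC and Youden-optimal cutoff for a binary outcome
#'
#' AUC via the Mann-Whitney identity (ties count 0.5); the cutoff maximizes
#' Youden's J over midpoints between consecutive unique marker values, ties
#' breaking toward the lower cutoff; the AUC CI is DeLong's.
#'
#' @param marker Numeric marker.
#' @param label Binary outcome (1 = positive class, higher marker expected).
#' @return Tibble `auc, auc_low, auc_high, cutoff, sens, spec`.
#' @export
roc_cutoff <- function(marker, label) {
  label <- as.integer(label)
  if (length(unique(label)) != 2) abort("Both classes must be present.")
  x <- marker[label == 1]; y <- marker[label == 0]
  r <- rank(c(x, y))
  auc <- (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
    (length(x) * length(y))
  uq <- sort(unique(marker))
  cand <- c(uq[1] - 1, (uq[-length(uq)] + uq[-1]) / 2, uq[length(uq)] + 1)
  j <- purrr::map_dbl(cand, function(cut) {
    mean(x >= cut) + mean(y < cut) - 1
  })
  best <- which.max(j)  # first max = lower cutoff on ties
  ci <- suppressWarnings(suppressMessages(
    pROC::ci.auc(pROC::roc(label, marker, quiet = TRUE, direction = "<"),
                 method = "delong")))
  tibble(auc = auc, auc_low = as.numeric(ci[1]), auc_high = as.numeric(ci[3]),
         cutoff = cand[best],
         sens = mean(x >= cand[best]), spec = mean(y < cand[best]))
}
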