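test_that("contingency tests: independence limit and margins guard", {
  even <- rbind(c(10, 10), c(10, 10))
  res <- pearson_chi2(even)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_error(pearson_chi2(rbind(c(0, 0), c(5, 5))), "margin")

  expect_equal(fisher_exact(rbind(c(1, 0), c(0, 1)))$p, 1)
  # enumeration oracle on random small tables
  set.seed(1)
  for (k in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p, oracle_fisher_p(tab), tolerance = 1e-8)
  }
})

test_that("location tests behave at the null and against enumeration", {
  x <- c(1, 2, 3, 4)
  res <- t_test2(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  set.seed(2)
  strong <- t_test2(rnorm(1000), rnorm(1000, 1))
  expect_lt(strong$p, 1e-10)

  # U equals pair counting on tiny fixtures
  for (k in 1:10) {
    a <- sample(1:20, 6, replace = TRUE)
    b <- sample(1:20, 7, replace = TRUE)
    u_pairs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    expect_equal(unname(mann_whitney(a, b)$U), u_pairs)
  }
})

test_that("KM estimator: steps, median rule, not-reached convention", {
  d <- tibble::tibble(time = 1:10, event = 1)
  km <- km_estimate(d)
  expect_equal(km$curve$surv, seq(0.9, 0, by = -0.1))
  expect_equal(km$median$median, 5)  # first time S(t) <= 0.5

  d2 <- tibble::tibble(time = 1:10, event = c(rep(1, 3), rep(0, 7)))
  expect_true(is.na(km_estimate(d2)$median$median))  # curve stays > 0.5
})

test_that("log-rank: null on identical groups, power under separation", {
  d <- tibble::tibble(time = rep(1:10, 2), event = 1)
  grp <- rep(c("a", "b"), each = 10)
  res <- logrank_test(d, grp)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-9)

  set.seed(3)
  n <- 400
  g <- rep(0:1, each = n / 2)
  t <- rexp(n, 0.02 * ifelse(g == 1, 5, 1))
  km <- km_estimate(tibble::tibble(time = t, event = 1), g)
  meds <- km$median$median
  expect_lt(abs(meds[km$median$group == "0"] - log(2) / 0.02), 0.15 * log(2) / 0.02)
  expect_lt(abs(meds[km$median$group == "1"] - log(2) / 0.1), 0.15 * log(2) / 0.1)
  expect_lt(logrank_test(tibble::tibble(time = t, event = 1), g)$p, 1e-10)
})

test_that("Cox fit recovers a true HR of 5 and is calibrated at the null", {
  set.seed(4)
  n <- 1000
  x <- rbinom(n, 1, 0.5)
  d <- tibble::tibble(time = rexp(n, 0.02 * exp(log(5) * x)), event = 1, x = x)
  td <- tidy(cox_fit(d, "x"))
  expect_gt(td$hr, 4)
  expect_lt(td$hr, 6.25)
  expect_true(td$hr_low < td$hr & td$hr < td$hr_high)
  expect_equal(td$hr, exp(td$coef))

  set.seed(5)
  zs <- replicate(40, {
    dd <- tibble::tibble(time = rexp(100, 0.05), event = 1,
                         x = rbinom(100, 1, 0.5))
    tidy(cox_fit(dd, "x"))$z
  })
  expect_lte(sum(abs(zs) >= 3), 1)

  expect_error(cox_fit(tibble::tibble(time = 1:5, event = 0, x = c(0, 1, 0, 1, 0)), "x"),
               "one event")
  expect_error(cox_fit(tibble::tibble(time = 1:5, event = 1, x = 1), "x"),
               "Constant")
})

test_that("proportional-hazards diagnostics detect crossing hazards only", {
  set.seed(6)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  # proportional world
  d_ok <- tibble::tibble(time = rexp(n, 0.05 * exp(0.7 * x)), event = 1, x = x)
  p_ok <- ph_test(cox_fit(d_ok, "x"))
  expect_true(all(p_ok$p >= 0 & p_ok$p <= 1))
  # crossing hazards: shape 0.5 vs 2 Weibull with a common scale
  t_bad <- ifelse(x == 1, rweibull(n, 0.5, 10), rweibull(n, 2, 10))
  p_bad <- ph_test(cox_fit(tibble::tibble(time = t_bad, event = 1, x = x), "x"))
  expect_lt(p_bad$p[p_bad$term == "x"], 0.01)
})

test_that("nested likelihood-ratio test: zero at equality, power for signal", {
  set.seed(7)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  z <- rnorm(n)
  d <- tibble::tibble(time = rexp(n, 0.05 * exp(1 * x)), event = 1, x = x, z = z)
  full <- cox_fit(d, c("x", "z"))
  x_only <- cox_fit(d, "x")
  same <- lrt_nested(x_only, x_only)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)
  gain <- lrt_nested(full, cox_fit(d, "z"))
  expect_lt(gain$p, 1e-4)           # adding the real predictor
  noise <- lrt_nested(full, x_only) # adding pure noise
  expect_gt(noise$p, 0.001)
  expect_error(lrt_nested(x_only, full), "subset")
})

test_that("concordance index: bounds, ties, brute-force oracle", {
  d <- tibble::tibble(time = c(5, 3, 8, 1, 9, 2), event = 1)
  perfect <- -d$time  # higher marker = earlier event
  expect_equal(c_index(perfect, d), 1)
  expect_equal(c_index(rep(1, 6), d), 0.5)

  set.seed(8)
  for (k in 1:5) {
    n <- 60
    tm <- rexp(n, 0.1); ev <- rbinom(n, 1, 0.7)
    mk <- round(rnorm(n), 1)  # rounding induces ties
    dd <- tibble::tibble(time = tm, event = ev)
    expect_equal(c_index(mk, dd), oracle_c_index(mk, tm, ev))
    # independent cross-check against the survival package
    conc <- survival::concordance(survival::Surv(tm, ev) ~ mk, reverse = TRUE)
    expect_equal(c_index(mk, dd), unname(conc$concordance))
  }
})

test_that("NRI arithmetic: null, perfect, and a hand-computed fixture", {
  out <- c(1, 1, 1, 0, 0, 0)
  r <- c(0.1, 0.5, 0.7, 0.5, 0.7, 0.1)
  expect_equal(nri(r, r, out, c(0.2, 0.6))$nri_total, 0)

  # perfect reclassification attains the upper bound of 2
  r_old <- c(0.1, 0.1, 0.1, 0.9, 0.9, 0.9)
  r_new <- c(0.9, 0.9, 0.9, 0.1, 0.1, 0.1)
  expect_equal(nri(r_old, r_new, out, 0.5)$nri_total, 2)

  # hand-computed: P(up|ev)=2/3, P(down|ev)=0, P(down|ne)=2/3, P(up|ne)=0
  new <- c(0.5, 0.7, 0.7, 0.1, 0.5, 0.1)
  res <- nri(r, new, out, c(0.2, 0.6))
  expect_equal(res$nri_event, 2 / 3)
  expect_equal(res$nri_nonevent, 2 / 3)
  expect_equal(res$nri_total, 4 / 3)
})

test_that("ROC cutoff: Mann-Whitney identity and Youden point", {
  lab <- c(rep(1, 5), rep(0, 5))
  mk <- c(6:10, 1:5)
  res <- roc_cutoff(mk, lab)
  expect_equal(res$auc, 1)
  expect_gt(res$cutoff, 5)
  expect_lte(res$cutoff, 6)
  expect_equal(res$sens, 1)
  expect_equal(res$spec, 1)

  set.seed(9)
  for (k in 1:5) {
    mk2 <- round(rnorm(40), 1)
    lab2 <- rbinom(40, 1, 0.4)
    if (length(unique(lab2)) < 2) next
    u <- unname(mann_whitney(mk2[lab2 == 1], mk2[lab2 == 0])$U)
    expect_equal(roc_cutoff(mk2, lab2)$auc,
                 u / (sum(lab2 == 1) * sum(lab2 == 0)))
  }
  expect_error(roc_cutoff(1:4, rep(1, 4)), "Both classes")
})
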