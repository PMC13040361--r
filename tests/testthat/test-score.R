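test_that("segment-level Z and length are computed as stated", {
  g <- toy_genome(c(chr1 = 1e6), centromeres = list(chr1 = c(999998, 999999)))
  grid <- build_bin_grid(g, 2e5)
  grid$centromeric <- FALSE; grid$arm <- "p"
  z <- z_tbl(rep(2, 5), grid)
  segs <- tibble::tibble(sample = "s1", chrom = "chr1", arm = "p",
                         start = 0, end = 1e6, start_bin = 1L, end_bin = 5L,
                         n_bins = 5L, seg_mean = 2)
  sz <- segment_z(z, segs)
  expect_equal(sz$L, 1)
  expect_equal(sz$z_seg, 2)

  z0 <- z_tbl(rep(0, 5), grid)
  expect_equal(segment_z(z0, segs)$z_seg, 0)

  # brute-force equality on a random fixture
  set.seed(1)
  zr <- z_tbl(rnorm(5), grid)
  segs2 <- tibble::tibble(sample = "s1", chrom = "chr1", arm = "p",
                          start = c(0, 6e5), end = c(6e5, 1e6),
                          start_bin = c(1L, 4L), end_bin = c(3L, 5L),
                          n_bins = c(3L, 2L), seg_mean = NA_real_)
  sz2 <- segment_z(zr, segs2)
  expect_equal(sz2$z_seg, c(mean(zr$z[1:3]), mean(zr$z[4:5])))
})

test_that("CIN score follows sum(L x |Z|) with the z_min gate", {
  seg1 <- tibble::tibble(sample = "s", n_bins = 10L, L = 50, z_seg = 1.5,
                         start = 0, end = 5e7)
  expect_equal(cin_score(seg1)$cin_score, 0)          # below z_min

  seg2 <- tibble::tibble(sample = "s", n_bins = 10L, L = 100, z_seg = -5,
                         start = 0, end = 1e8)
  expect_equal(cin_score(seg2)$cin_score, 500)        # |.| convention
  expect_equal(cin_score(seg2, use_abs = FALSE)$cin_score, -500)
  expect_equal(cin_score(seg2, units = "bp")$cin_score, 5e8)
  expect_equal(cin_score(seg2, units = "bins")$cin_score, 50)

  # adding a qualifying segment strictly increases the score
  seg3 <- dplyr::bind_rows(seg2, tibble::tibble(
    sample = "s", n_bins = 5L, L = 10, z_seg = 3, start = 0, end = 1e7))
  expect_gt(cin_score(seg3)$cin_score, cin_score(seg2)$cin_score)
  # ordering is irrelevant
  expect_equal(cin_score(seg3[2:1, ])$cin_score, cin_score(seg3)$cin_score)
})

test_that("arm Z-scores localize implanted shifts", {
  g <- toy_genome(c(chr1 = 1e7, chr2 = 1e7))
  grid <- build_bin_grid(g, 2e5)
  z <- z_tbl(ifelse(grid$chrom == "chr1" & grid$arm %in% "q", 3, 0), grid)
  az <- arm_z(z)
  expect_equal(az$arm_z[az$arm == "chr1q"], 3)
  expect_equal(az$arm_z[az$arm != "chr1q"], rep(0, 3))

  # whole-chromosome event: p and q agree
  z2 <- z_tbl(ifelse(grid$chrom == "chr2", 2.5, 0), grid)
  az2 <- arm_z(z2)
  expect_equal(az2$arm_z[az2$arm == "chr2p"], az2$arm_z[az2$arm == "chr2q"])
})

test_that("positivity and CIN class boundary conventions", {
  expect_true(arm_positive(1.568, 1.568))    # inclusive
  expect_false(arm_positive(0, 1.568))
  expect_equal(classify_cin(6486.723, 6486.722), "high")  # strictly above
  expect_equal(classify_cin(6486.722, 6486.722), "low")
  expect_equal(classify_cin(0, 1), "low")
})

test_that("per-segment group comparison flags implanted shifts only", {
  set.seed(2)
  n <- 25
  m <- cbind(seg_a = rnorm(2 * n), seg_b = rnorm(2 * n))
  grp <- rep(c(TRUE, FALSE), each = n)
  m[grp, "seg_b"] <- m[grp, "seg_b"] + 3
  res <- segment_group_test(m, grp)
  expect_false(res$significant[res$segment == "seg_a"])
  expect_true(res$significant[res$segment == "seg_b"])
  expect_gt(res$mean_diff[res$segment == "seg_b"], 2)
  # flag is exactly the log10(p) < -1.3 rule
  expect_equal(res$significant, res$log10_p < -1.3)

  same <- segment_group_test(cbind(s = rep(1:25, 2)), rep(c(TRUE, FALSE), each = 25))
  expect_false(same$significant)
  expect_gt(same$log10_p, -0.1)
  expect_error(segment_group_test(m, rep(TRUE, 2 * n)), "2 samples")
})

test_that("maxstat cutoff separates constructed clusters and matches the oracle", {
  # early relapsers score 1..10, never-relapsers score 101..110
  scores <- c(1:10, 101:110)
  times <- c(2:11, rep(100, 10))
  events <- c(rep(1, 10), rep(0, 10))
  res <- max_sel_rank_cutoff(scores, times, events)
  expect_gt(res$cutoff, 10)
  expect_lt(res$cutoff, 101)
  expect_lt(res$approx_p, 0.01)

  set.seed(3)
  for (rep in 1:10) {
    n <- 40
    sc <- rnorm(n)
    tm <- rexp(n, 0.05 * exp(0.5 * (sc > 0)))
    cn <- runif(n, 5, 60)
    d_time <- pmin(tm, cn); d_ev <- as.integer(tm <= cn)
    if (sum(d_ev) < 2 || sum(1 - d_ev) < 1) next
    got <- max_sel_rank_cutoff(sc, d_time, d_ev)
    want <- oracle_maxstat(sc, d_time, d_ev)
    expect_equal(got$max_statistic, unname(want["stat"]), tolerance = 1e-10)
    expect_equal(got$cutoff, unname(want["cut"]), tolerance = 1e-10)
  }

  expect_error(max_sel_rank_cutoff(1:5, 1:5, rep(1, 5)), "10 samples")
  expect_error(max_sel_rank_cutoff(1:12, 1:12, rep(1, 12)), "censored")
})

test_that("maxstat tidy/glance expose the candidate scan", {
  scores <- c(1:10, 101:110)
  times <- c(2:11, rep(100, 10))
  events <- c(rep(1, 10), rep(0, 10))
  res <- max_sel_rank_cutoff(scores, times, events)
  td <- tidy(res)
  expect_true(all(c("cutpoint", "statistic") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$cutoff, res$cutoff)
  expect_equal(max(td$statistic), gl$max_statistic)
})
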