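test_that("bin grid tiles chromosomes exactly, remainder bin last", {
  g1 <- toy_genome(c(chr1 = 1e6), centromeres = list(chr1 = c(4e5, 6e5)))
  grid <- build_bin_grid(g1, 2e5)
  expect_equal(nrow(grid), 5)
  expect_equal(grid$start, seq(0, 8e5, by = 2e5))
  expect_equal(grid$end - grid$start, rep(2e5, 5))

  g2 <- toy_genome(c(chr1 = 1.1e6), centromeres = list(chr1 = c(4e5, 6e5)))
  grid2 <- build_bin_grid(g2, 2e5)
  expect_equal(nrow(grid2), 6)
  expect_equal(grid2$end[6] - grid2$start[6], 1e5)
  # widths sum to chromosome length
  expect_equal(sum(grid2$end - grid2$start), 1.1e6)
})

test_that("centromere-overlapping bins are flagged and excluded from arms", {
  g <- toy_genome(c(chr1 = 1e6, chr2 = 6e5),
                  centromeres = list(chr1 = c(4e5, 6e5), chr2 = c(2e5, 4e5)))
  grid <- build_bin_grid(g, 2e5)
  expected <- tibble::tibble(
    chrom = c(rep("chr1", 5), rep("chr2", 3)),
    start = c(seq(0, 8e5, 2e5), seq(0, 4e5, 2e5)),
    arm = c("p", "p", NA, "q", "q", "p", NA, "q"))
  expect_equal(grid$chrom, expected$chrom)
  expect_equal(grid$start, expected$start)
  expect_equal(grid$arm, expected$arm)
  expect_equal(grid$centromeric, is.na(expected$arm))
  # p-arm bins all end at or before the centromere start
  expect_true(all(grid$end[grid$arm %in% "p" & grid$chrom == "chr1"] <= 4e5))
})

test_that("invalid grids and genomes are rejected", {
  g <- toy_genome(c(chr1 = 1e6))
  expect_error(build_bin_grid(g, 0), "positive")
  expect_error(toy_genome(c(chr1 = 1e6), centromeres = list(chr1 = c(5e5, 2e6))),
               "centromere")
  expect_error(toy_genome(setNames(c(1e6, 1e6), c("a", "a"))), "unique")
})

test_that("coverage tables round-trip and off-grid rows are named", {
  grid <- toy_grid_5()
  cov <- cov_tbl(list(s1 = c(10, 12, 9, 11, 13), s2 = c(5, 6, 7, 8, 9)), grid)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coverage_table(cov, path)
  back <- read_coverage_table(path, grid)
  expect_equal(back$coverage, cov$coverage)
  expect_equal(back$sample, cov$sample)
  expect_equal(nrow(attr(back, "missing_bins")), 0)

  bad <- cov
  bad$start[2] <- 123
  write_coverage_table(bad, path)
  expect_error(read_coverage_table(path, grid), "Row 2")

  dup <- rbind(cov, cov[1, ])
  write_coverage_table(dup, path)
  expect_error(read_coverage_table(path, grid), "Duplicate")
})

test_that("reads_to_bins uses half-open bins and conserves reads", {
  grid <- toy_grid_5()
  reads <- tibble::tibble(chrom = "chr1", start = c(0, 199999, 200000))
  prof <- reads_to_bins(reads, grid)
  expect_equal(prof$coverage, c(2, 1, 0, 0, 0))

  empty <- reads_to_bins(tibble::tibble(chrom = character(), start = numeric()), grid)
  expect_equal(empty$coverage, rep(0, 5))

  set.seed(42)
  many <- tibble::tibble(chrom = "chr1", start = floor(runif(10000, 0, 1e6)))
  prof2 <- reads_to_bins(many, grid)
  expect_equal(sum(prof2$coverage), 10000)

  odd <- tibble::tibble(chrom = c("chr1", "chrX"), start = c(0, 0))
  expect_message(prof3 <- reads_to_bins(odd, grid), "Skipped 1")
  expect_equal(attr(prof3, "skipped"), 1)
  expect_equal(sum(prof3$coverage), 1)
})

test_that("SEG and BED writers are mutually inverse and offset by one", {
  grid <- toy_grid_5()
  segs <- tibble::tibble(sample = "s1", chrom = "chr1", start = 0, end = 1e6,
                         n_bins = 5, seg_mean = 1.25)
  seg_path <- withr::local_tempfile(fileext = ".seg")
  write_segments_seg(segs, seg_path)
  raw <- readr::read_tsv(seg_path, show_col_types = FALSE)
  expect_equal(raw$num.mark, 5)
  expect_equal(raw$loc.start, 1)          # SEG start = BED start + 1
  back <- read_segments_seg(seg_path)
  expect_equal(back$start, segs$start)
  expect_equal(back$end, segs$end)

  bed_path <- withr::local_tempfile(fileext = ".bed")
  write_bins_bed(grid, 1:5, bed_path)
  bed <- read_bins_bed(bed_path)
  expect_equal(bed$start, grid$start)
  expect_equal(bed$end, grid$end)
  expect_equal(bed$value, 1:5)

  overlapping <- tibble::tibble(sample = "s1", chrom = "chr1",
                                start = c(0, 1e5), end = c(2e5, 3e5),
                                n_bins = c(1, 1), seg_mean = c(0, 0))
  expect_error(write_segments_seg(overlapping, seg_path), "Overlap")
})
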