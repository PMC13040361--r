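#' Read and write per-bin coverage tables
#'
#' The on-disk format is tab-separated with header
#' `sample  chrom  start  end  coverage`; coordinates are 0-based half-open
#' and must match the bin grid exactly. Samples are returned in file order.
#'
#' @param path File path.
#' @param grid Bin grid from [build_bin_grid()].
#' @return Long tibble `sample, bin, chrom, start, end, coverage`, one row per
#'   (sample, bin) present in the file. Bins of the grid missing for a sample
#'   are reported via the `missing_bins` attribute (tibble sample/bin).
#' @export
read_coverage_table <- function(path, grid) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(),
    chrom = readr::col_character(),
    start = readr::col_double(),
    end = readr::col_double(),
    coverage = readr::col_double()
  ))
  if (any(!is.finite(raw$coverage)) || any(raw$coverage < 0)) {
    abort("Non-numeric or negative coverage values in file.")
  }
  key <- paste(raw$chrom, raw$start, raw$end)
  gkey <- paste(grid$chrom, grid$start, grid$end)
  hit <- match(key, gkey)
  if (anyNA(hit)) {
    bad <- which(is.na(hit))[1]
    abort(sprintf(
      "Row %d (%s:%s-%s) does not match any grid bin.",
      bad, raw$chrom[bad], format(raw$start[bad], scientific = FALSE),
      format(raw$end[bad], scientific = FALSE)))
  }
  if (anyDuplicated(cbind(raw$sample, hit))) {
    abort("Duplicate (sample, bin) rows in coverage file.")
  }
  out <- raw |>
    mutate(bin = hit,
           sample = factor(.data$sample, levels = unique(raw$sample))) |>
    arrange(.data$sample, .data$bin) |>
    mutate(sample = as.character(.data$sample)) |>
    select("sample", "bin", "chrom", "start", "end", "coverage")
  missing <- tidyr::expand_grid(sample = unique(raw$sample), bin = grid$bin) |>
    anti_join(out, by = c("sample", "bin"))
  if (nrow(missing) > 0) {
    warn(sprintf("%d (sample, bin) combinations missing from coverage file.",
                 nrow(missing)))
  }
  attr(out, "missing_bins") <- missing
  out
}

#' @rdname read_coverage_table
#' @param coverage Long coverage tibble as returned by [read_coverage_table()]
#'   or the simulators.
#' @export
write_coverage_table <- function(coverage, path) {
  readr::write_tsv(coverage[, c("sample", "chrom", "start", "end", "coverage")],
                   path)
  invisible(path)
}

#' Count aligned-read start positions into grid bins
#'
#' Adapter from BED-like aligned positions to a coverage profile: a read is
#' assigned to the bin containing its start (0-based half-open). Reads on
#' chromosomes absent from the grid are skipped and counted.
#'
#' @param reads Tibble with columns `chrom`, `start` (a BED `end` column is
#'   ignored), or a path to a BED file.
#' @param grid Bin grid.
#' @param sample Sample id for the output profile.
#' @return Coverage tibble (one row per grid bin); skipped-read count in the
#'   `skipped` attribute.
#' @export
reads_to_bins <- function(reads, grid, sample = "sample") {
  if (is.character(reads) && length(reads) == 1) {
    reads <- readr::read_tsv(reads, col_names = FALSE,
                             col_types = readr::cols(.default = readr::col_guess()))
    names(reads)[1:2] <- c("chrom", "start")
  }
  known <- reads$chrom %in% unique(grid$chrom)
  skipped <- sum(!known)
  if (skipped > 0) {
    inform(sprintf("Skipped %d reads on chromosomes absent from the grid.", skipped))
  }
  reads <- reads[known, , drop = FALSE]
  counts <- integer(nrow(grid))
  for (ch in unique(grid$chrom)) {
    gsel <- grid$chrom == ch
    rsel <- reads$chrom == ch
    if (!any(rsel)) next
    starts <- grid$start[gsel]
    last_end <- max(grid$end[gsel])
    pos <- reads$start[rsel]
    pos <- pos[pos >= 0 & pos < last_end]
    idx <- findInterval(pos, starts)  # 1-based bin within chromosome
    counts[gsel] <- counts[gsel] + tabulate(idx, nbins = sum(gsel))
  }
  out <- tibble(sample = sample, bin = grid$bin, chrom = grid$chrom,
                start = grid$start, end = grid$end, coverage = as.numeric(counts))
  attr(out, "skipped") <- skipped
  out
}

#' Write segments as SEG, and bins as BED
#'
#' SEG uses 1-based inclusive starts per convention (`loc.start = BED start +
#' 1`); BED stays 0-based half-open. Re-reading either reproduces coordinates
#' exactly.
#'
#' @param segments Segment tibble with `sample, chrom, start, end, n_bins,
#'   seg_mean` (as produced by [segment_genome()]).
#' @param path Output file.
#' @export
write_segments_seg <- function(segments, path) {
  overlap <- segments |>
    group_by(.data$sample, .data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(bad = any(.data$start < dplyr::lag(.data$end, default = -Inf)),
              .groups = "drop")
  if (any(overlap$bad)) abort("Overlapping segments; refusing to write SEG.")
  seg <- tibble(
    ID = segments$sample, chrom = segments$chrom,
    loc.start = segments$start + 1, loc.end = segments$end,
    num.mark = segments$n_bins, seg.mean = segments$seg_mean)
  readr::write_tsv(seg, path)
  invisible(path)
}

#' @rdname write_segments_seg
#' @export
read_segments_seg <- function(path) {
  seg <- readr::read_tsv(path, col_types = readr::cols(
    ID = readr::col_character(), chrom = readr::col_character(),
    loc.start = readr::col_double(), loc.end = readr::col_double(),
    num.mark = readr::col_double(), seg.mean = readr::col_double()))
  tibble(sample = seg$ID, chrom = seg$chrom,
         start = seg$loc.start - 1, end = seg$loc.end,
         n_bins = seg$num.mark, seg_mean = seg$seg.mean)
}

#' @rdname write_segments_seg
#' @param grid Bin grid.
#' @param values Numeric vector, one value per grid bin.
#' @export
write_bins_bed <- function(grid, values, path) {
  stopifnot(length(values) == nrow(grid))
  readr::write_tsv(tibble(chrom = grid$chrom,
                          start = format(grid$start, scientific = FALSE, trim = TRUE),
                          end = format(grid$end, scientific = FALSE, trim = TRUE),
                          value = values),
                   path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_segments_seg
#' @export
read_bins_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                         col_types = "cddd")
  bed
}
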