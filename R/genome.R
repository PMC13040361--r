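#' Genome models and bin grids
#'
#' A genome model is a tibble with one row per chromosome: `chrom`, `length`
#' (bp), and the centromere interval `cen_start`/`cen_end` (bp) separating the
#' p from the q arm. All coordinates are 0-based half-open internally. The
#' shipped default is an hg19-like table of the 22 autosomes; sex chromosomes
#' are excluded by default because mixed-sex control panels make their
#' coverage bimodal.
#'
#' @param path TSV with columns `chrom`, `length`, `cen_start`, `cen_end`.
#' @return A tibble with class `cin_genome`.
#' @export
read_genome_model <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    length = readr::col_double(),
    cen_start = readr::col_double(),
    cen_end = readr::col_double()
  ))
  validate_genome(tbl)
}

#' @rdname read_genome_model
#' @export
hg19_genome <- function() {
  path <- system.file("extdata", "genome_hg19_autosomes.tsv",
                      package = "cinscore", mustWork = TRUE)
  read_genome_model(path)
}

#' Build a small toy genome for examples and tests
#'
#' @param lengths Named numeric vector of chromosome lengths (bp).
#' @param centromeres Optional named list of `c(start, end)`; defaults to a
#'   20% slice around each chromosome midpoint.
#' @return A `cin_genome` tibble.
#' @export
toy_genome <- function(lengths, centromeres = NULL) {
  chroms <- names(lengths)
  if (is.null(chroms) || any(chroms == "")) {
    abort("`lengths` must be a named vector of chromosome lengths.")
  }
  cen <- purrr::map(chroms, function(ch) {
    if (!is.null(centromeres) && ch %in% names(centromeres)) {
      centromeres[[ch]]
    } else {
      mid <- lengths[[ch]] / 2
      c(mid - lengths[[ch]] * 0.1, mid + lengths[[ch]] * 0.1)
    }
  })
  validate_genome(tibble(
    chrom = chroms,
    length = as.numeric(lengths),
    cen_start = purrr::map_dbl(cen, 1),
    cen_end = purrr::map_dbl(cen, 2)
  ))
}

validate_genome <- function(tbl) {
  stopifnot(all(c("chrom", "length", "cen_start", "cen_end") %in% names(tbl)))
  if (anyDuplicated(tbl$chrom)) abort("Chromosome names must be unique.")
  bad <- with(tbl, !(cen_start > 0 & cen_end > cen_start & cen_end < length))
  if (any(bad)) {
    abort(paste0("Invalid centromere for: ",
                 paste(tbl$chrom[bad], collapse = ", "),
                 " (need 0 < cen_start < cen_end < length)."))
  }
  class(tbl) <- c("cin_genome", class(tbl))
  tbl
}

#' Tile a genome into fixed-width bins
#'
#' Bins are 0-based half-open, `bin_size` wide except possibly the last bin of
#' each chromosome. Each bin is assigned to the p arm (ends at or before the
#' centromere start), the q arm (starts at or after the centromere end), or is
#' flagged `centromeric` and excluded from arm assignment and all downstream
#' normalization, segmentation and scoring.
#'
#' @param genome A `cin_genome` tibble (see [read_genome_model()]).
#' @param bin_size Bin width in bp (default 200 kb).
#' @return Tibble with columns `bin` (1-based index over the whole grid),
#'   `chrom`, `start`, `end`, `arm` (`"p"`, `"q"` or `NA`), `centromeric`.
#' @export
build_bin_grid <- function(genome, bin_size = 200000) {
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0) {
    abort("`bin_size` must be a single positive number.")
  }
  if (nrow(genome) == 0) abort("`genome` is empty.")
  grid <- purrr::pmap(genome, function(chrom, length, cen_start, cen_end, ...) {
    starts <- seq(0, length - 1, by = bin_size)
    ends <- pmin(starts + bin_size, length)
    centromeric <- starts < cen_end & ends > cen_start
    arm <- dplyr::case_when(
      centromeric ~ NA_character_,
      ends <= cen_start ~ "p",
      starts >= cen_end ~ "q"
    )
    tibble(chrom = chrom, start = starts, end = ends,
           arm = arm, centromeric = centromeric)
  }) |>
    purrr::list_rbind() |>
    mutate(bin = dplyr::row_number(), .before = 1)
  attr(grid, "bin_size") <- bin_size
  class(grid) <- c("cin_grid", class(grid))
  grid
}

#' Chromosome-arm labels of a grid, e.g. "chr8q"
#' @param grid A bin grid from [build_bin_grid()].
#' @return Character vector, `NA` for centromeric bins.
#' @export
arm_label <- function(grid) {
  ifelse(is.na(grid$arm), NA_character_, paste0(grid$chrom, grid$arm))
}
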