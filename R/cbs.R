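#' Circular binary segmentation of one series
#'
#' In-house implementation of the Olshen-Venkatraman recursion: for the
#' current interval, find the arc maximizing the circular two-sample pooled-t
#' statistic between the arc and its complement; accept the split iff its
#' permutation p-value, `(1 + #{perm max-t >= observed}) / (1 + n_perm)`, is
#' below `alpha` and every resulting piece has at least `min_width` bins;
#' recurse into the pieces. Ties in the max-t search break toward the smaller
#' left index, then the smaller right index, so output is deterministic under
#' a fixed seed.
#'
#' @param series Numeric vector (per-bin Z or log-ratio for one chromosome
#'   arm); must be finite.
#' @param alpha Split significance level.
#' @param n_perm Number of permutations per split test.
#' @param min_width Minimum segment width in bins.
#' @param seed Optional integer seed for the permutation stream.
#' @return Tibble `start_bin, end_bin, n_bins, seg_mean` with 1-based
#'   inclusive indices into `series`.
#' @export
cbs_segment <- function(series, alpha = 0.01, n_perm = 1000, min_width = 3,
                        seed = NULL) {
  stopifnot(length(series) >= 1, all(is.finite(series)),
            alpha > 0, alpha < 1, n_perm >= 100, min_width >= 1)
  if (!is.null(seed)) set.seed(seed)
  bounds <- cbs_recurse(series, 1L, length(series), alpha, n_perm, min_width)
  tibble(
    start_bin = purrr::map_int(bounds, 1),
    end_bin = purrr::map_int(bounds, 2)) |>
    mutate(n_bins = .data$end_bin - .data$start_bin + 1L,
           seg_mean = purrr::map2_dbl(.data$start_bin, .data$end_bin,
                                      ~ mean(series[.x:.y])))
}

cbs_recurse <- function(x, lo, hi, alpha, n_perm, min_width) {
  n <- hi - lo + 1L
  if (n < 2L * min_width) return(list(c(lo, hi)))
  res <- cbs_split_test(x[lo:hi], min_width, n_perm, alpha)
  if (res$i < 0 || res$p >= alpha) return(list(c(lo, hi)))
  cuts <- unique(c(lo, lo + res$i, lo + res$j, hi + 1L))
  cuts <- sort(cuts)
  pieces <- list()
  for (k in seq_len(length(cuts) - 1L)) {
    pieces <- c(pieces, cbs_recurse(x, cuts[k], cuts[k + 1L] - 1L,
                                    alpha, n_perm, min_width))
  }
  pieces
}

#' Merge adjacent segments with near-equal means
#'
#' Stabilizer analogous to DNAcopy's undo options: adjacent segments whose
#' mean difference is below `merge_sd` times the pooled within-segment
#' standard deviation are merged, iterating until stable (the closest pair
#' merges first).
#'
#' @param segments Segment tibble from [cbs_segment()] (one series).
#' @param series The segmented series.
#' @param merge_sd Merge threshold in within-segment sd units.
#' @return Pruned segment tibble; a partition of the same bins.
#' @export
prune_segments <- function(segments, series, merge_sd = 1.5) {
  seg <- as.data.frame(segments)
  repeat {
    if (nrow(seg) < 2) break
    resid <- unlist(lapply(seq_len(nrow(seg)), function(k) {
      v <- series[seg$start_bin[k]:seg$end_bin[k]]
      v - mean(v)
    }))
    pooled <- if (length(resid) > nrow(seg)) {
      sqrt(sum(resid^2) / (length(resid) - nrow(seg)))
    } else 0
    gaps <- abs(diff(seg$seg_mean))
    thr <- max(merge_sd * pooled, 1e-12)  # exact-equal means always merge
    k <- which.min(gaps)  # merge the closest admissible pair
    if (!is.finite(gaps[k]) || gaps[k] >= thr) break
    seg$end_bin[k] <- seg$end_bin[k + 1]
    seg$n_bins[k] <- seg$end_bin[k] - seg$start_bin[k] + 1
    seg$seg_mean[k] <- mean(series[seg$start_bin[k]:seg$end_bin[k]])
    seg <- seg[-(k + 1), ]
  }
  as_tibble(seg)
}

#' Segment a whole Z-profile genome-wide
#'
#' Applies [cbs_segment()] plus [prune_segments()] independently to every
#' contiguous run of usable bins (chromosome arms; masked centromeric or
#' zero-variance bins are excised first, so segments never span the
#' centromere). Start/end coordinates are genomic (0-based half-open, from the
#' first/last bin of the segment).
#'
#' @param zprofile Long Z tibble from [zscore_bins()], one or more samples.
#' @param grid Bin grid.
#' @param alpha,n_perm,min_width,merge_sd Segmentation parameters.
#' @param seed Optional integer seed.
#' @return Tibble `sample, chrom, arm, start, end, start_bin, end_bin, n_bins,
#'   seg_mean` (bin indices refer to the grid).
#' @export
segment_genome <- function(zprofile, grid, alpha = 0.01, n_perm = 1000,
                           min_width = 3, merge_sd = 1.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  zprofile |>
    filter(.data$usable, is.finite(.data$z)) |>
    mutate(arm_id = paste0(.data$chrom, .data$arm)) |>
    group_by(.data$sample, .data$chrom, .data$arm, .data$arm_id) |>
    group_modify(function(df, key) {
      df <- arrange(df, .data$bin)
      segs <- cbs_segment(df$z, alpha = alpha, n_perm = n_perm,
                          min_width = min_width)
      segs <- prune_segments(segs, df$z, merge_sd = merge_sd)
      tibble(
        start = df$start[segs$start_bin],
        end = df$end[segs$end_bin],
        start_bin = df$bin[segs$start_bin],
        end_bin = df$bin[segs$end_bin],
        n_bins = segs$n_bins,
        seg_mean = segs$seg_mean)
    }) |>
    ungroup() |>
    select("sample", "chrom", "arm", "start", "end",
           "start_bin", "end_bin", "n_bins", "seg_mean") |>
    arrange(.data$sample, match(.data$chrom, unique(grid$chrom)), .data$start)
}
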