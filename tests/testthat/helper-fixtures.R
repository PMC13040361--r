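suppressMessages({
  library(dplyr)
  library(tibble)
})

# one 1-Mb chromosome, centromere 400-600 kb, 200-kb bins -> 5 bins
toy_grid_5 <- function() {
  g <- toy_genome(c(chr1 = 1e6), centromeres = list(chr1 = c(4e5, 6e5)))
  build_bin_grid(g, 2e5)
}

# small multi-chromosome genome for cohort-level work
toy_genome_4 <- function() {
  toy_genome(c(chr1 = 40e6, chr2 = 36e6, chr3 = 30e6, chr4 = 30e6))
}

# long coverage tibble from a named list of per-bin value vectors
cov_tbl <- function(values_by_sample, grid) {
  purrr::imap(values_by_sample, function(v, s) {
    tibble(sample = s, bin = grid$bin, chrom = grid$chrom,
           start = grid$start, end = grid$end, coverage = as.numeric(v))
  }) |> purrr::list_rbind()
}

# hand-built Z tibble over a grid
z_tbl <- function(z, grid, sample = "s1") {
  tibble(sample = sample, bin = grid$bin, chrom = grid$chrom,
         start = grid$start, end = grid$end, arm = grid$arm,
         z = ifelse(grid$centromeric, NA_real_, z),
         usable = !grid$centromeric)
}

# independent log-rank scores: per-event double loop over the risk set
oracle_logrank_scores <- function(times, events) {
  n <- length(times)
  a <- numeric(n)
  for (i in seq_len(n)) {
    haz <- 0
    for (j in seq_len(n)) {
      if (events[j] == 1 && times[j] <= times[i]) {
        haz <- haz + 1 / sum(times >= times[j])
      }
    }
    a[i] <- events[i] - haz
  }
  a
}

# exhaustive-scan oracle for the maximally selected rank statistic
oracle_maxstat <- function(scores, times, events, eps = 0.1) {
  n <- length(scores)
  a <- oracle_logrank_scores(times, events)
  uq <- sort(unique(scores))
  cand <- (uq[-length(uq)] + uq[-1]) / 2
  best <- c(cut = NA_real_, stat = -Inf)
  for (cut in cand) {
    m <- sum(scores <= cut)
    if (m / n < eps || m / n > 1 - eps) next
    S <- sum(a[scores <= cut])
    E <- m * mean(a)
    V <- m * (n - m) / (n * (n - 1)) * sum((a - mean(a))^2)
    st <- abs(S - E) / sqrt(V)
    if (st > best["stat"]) best <- c(cut = cut, stat = st)
  }
  best
}

# two-sided Fisher p by direct enumeration over tables with fixed margins
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(k) {
    choose(r1, k) * choose(r2, c1 - k) / choose(r1 + r2, c1)
  }, numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force Harrell C over all pairs
oracle_c_index <- function(marker, time, event) {
  conc <- 0; pairs <- 0
  n <- length(time)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    # usable iff the earlier time is an event (ties: event vs censored only)
    if (time[i] == time[j]) {
      if (event[i] + event[j] != 1) next
      ev <- if (event[i] == 1) i else j
      other <- if (ev == i) j else i
    } else {
      ev <- if (time[i] < time[j]) i else j
      other <- if (ev == i) j else i
      if (event[ev] != 1) next
    }
    pairs <- pairs + 1
    if (marker[ev] > marker[other]) conc <- conc + 1
    else if (marker[ev] == marker[other]) conc <- conc + 0.5
  }
  conc / pairs
}

# empirical cumulative/dynamic AUC by pair counting (no censoring)
oracle_cd_auc <- function(marker, time, horizon) {
  case <- time <= horizon
  num <- 0; den <- 0
  for (i in which(case)) for (j in which(!case)) {
    den <- den + 1
    num <- num + (marker[i] > marker[j]) + 0.5 * (marker[i] == marker[j])
  }
  num / den
}
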