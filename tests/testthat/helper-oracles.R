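# Independent brute-force oracles used to validate the analytical routines.
# These deliberately avoid the code paths they check.

# Exact two-sided p for an r x 2 contingency table by full enumeration of all
# tables with the observed margins (Freeman-Halton): sum the multivariate
# hypergeometric probabilities of every table no more probable than the
# observed one.
oracle_rx2_p <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(ncol(tab) == 2)
  row_sums <- rowSums(tab)
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  log_prob <- function(a) {
    sum(lchoose(row_sums, a)) - lchoose(n, c1)
  }
  obs <- log_prob(tab[, 1])
  r <- length(row_sums)
  total <- 0
  rec <- function(i, left, acc) {
    if (i == r) {
      if (left >= 0 && left <= row_sums[r]) {
        lp <- log_prob(c(acc, left))
        if (lp <= obs + 1e-7) total <<- total + exp(lp)
      }
      return(invisible())
    }
    lo <- max(0, left - sum(row_sums[(i + 1):r]))
    hi <- min(row_sums[i], left)
    if (lo > hi) return(invisible())
    for (a in lo:hi) rec(i + 1, left - a, c(acc, a))
  }
  rec(1, c1, integer(0))
  min(total, 1)
}

# All r x 2 tables with r rows and total count <= max_total, one
# representative per row-multiset (the exact p is invariant to row order).
oracle_enumerate_tables <- function(r, max_total) {
  rows <- list()
  for (a in 0:max_total) for (b in 0:(max_total - a)) {
    rows[[length(rows) + 1]] <- c(a, b)
  }
  out <- list()
  pick <- function(i, start, acc, left) {
    if (i > r) {
      tab <- do.call(rbind, acc)
      if (all(rowSums(tab) > 0)) out[[length(out) + 1]] <<- tab
      return(invisible())
    }
    for (j in start:length(rows)) {
      rw <- rows[[j]]
      if (sum(rw) <= left) pick(i + 1, j, c(acc, list(rw)), left - sum(rw))
    }
  }
  pick(1, 1, list(), max_total)
  out
}

# Kendall tau-b by O(n^2) concordant/discordant pair counting with tie
# correction.
oracle_kendall_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Kruskal-Wallis H and chi-square p from the rank formula with tie correction.
oracle_kruskal <- function(x, g) {
  n <- length(x)
  r <- rank(x)
  groups <- split(r, g)
  h <- 12 / (n * (n + 1)) * sum(vapply(groups, function(ri) {
    length(ri) * mean(ri)^2
  }, numeric(1))) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / corr
  list(h = h, p = pchisq(h, df = length(groups) - 1, lower.tail = FALSE))
}

# Dunn pairwise z statistics from first principles (shared ranks, tie term).
oracle_dunn <- function(x, g) {
  n <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  cls <- sort(unique(g))
  res <- list()
  for (i in seq_along(cls)) for (j in seq_along(cls)) {
    if (j <= i) next
    a <- r[g == cls[i]]; b <- r[g == cls[j]]
    z <- (mean(a) - mean(b)) /
      sqrt((n * (n + 1) / 12 - tie_term) * (1 / length(a) + 1 / length(b)))
    res[[length(res) + 1]] <- data.frame(
      comparison = paste(cls[i], "vs", cls[j]), z = z,
      p = 2 * pnorm(-abs(z))
    )
  }
  do.call(rbind, res)
}

# Adjusted Rand index between two labelings.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sum_comb <- function(v) sum(choose(v, 2))
  s_ab <- sum(choose(tab, 2))
  s_a <- sum_comb(rowSums(tab))
  s_b <- sum_comb(colSums(tab))
  n <- sum_comb(sum(tab))
  exp_idx <- s_a * s_b / n
  (s_ab - exp_idx) / ((s_a + s_b) / 2 - exp_idx)
}

# Small, fast simulation setup shared across tests.
small_config <- function(seed = 1, cohort_size = 60,
                         n_marker_cpgs_per_type = 4, ...) {
  simulation_config(
    seed = seed, n_celltypes = 4,
    n_marker_cpgs_per_type = n_marker_cpgs_per_type,
    n_background_cpgs = 120, n_ref_samples_per_type = 5,
    n_nonimmune_samples = 6, n_tumor_lines = 6, cohort_size = cohort_size, ...
  )
}
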