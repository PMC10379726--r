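# Independent brute-force oracles used to validate the statistical engines.

# Exact two-sided WMW p-value by full enumeration of all rank splits.
oracle_wmw <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  splits <- utils::combn(n, nx)
  w_obs <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
  w_all <- apply(splits, 2L, function(ix) {
    sum(rank(pooled)[ix]) - nx * (nx + 1) / 2
  })
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Cliff's delta by explicit double loop.
oracle_cliffs_delta <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) s <- s + sign(xi - yj)
  s / (length(x) * length(y))
}

# Kendall tau-b by O(n^2) concordance counting.
oracle_kendall_tau <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[i] - x[j]; dy <- y[i] - y[j]
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (sign(dx) == sign(dy)) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - count_tie_pairs(x)) * (n0 - count_tie_pairs(y)))
}

count_tie_pairs <- function(v) {
  sum(choose(table(v), 2))
}

# Two-sided Fisher's exact p by hypergeometric enumeration over all tables
# with the observed margins.
oracle_fisher <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Classical log-rank chi-square by direct 2x2 summation over event times.
oracle_logrank_chi2 <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  e <- sa * sb / choose(n, 2)
  (si - e) / ((sa + sb) / 2 - e)
}
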