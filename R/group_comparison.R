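# Rank-based two-group comparisons with nonparametric effect sizes:
# Wilcoxon-Mann-Whitney tests, Cliff's delta with confidence intervals,
# Fisher's exact 2x2 tests, per-feature sweeps and taxon set enrichment.

#' Two-sided Wilcoxon-Mann-Whitney test
#'
#' Exact p-value (via the shift algorithm of [stats::wilcox.test()]) when
#' the combined sample size is at most 30 and there are no ties; otherwise
#' the normal approximation with tie and continuity corrections.
#'
#' @param x,y Numeric value vectors for the two groups.
#' @return Two-sided p-value.
#' @export
wmw_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1L || length(y) < 1L) stop("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1L) return(1)  # degenerate: no information
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && (length(x) + length(y)) <= 30L
  suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value)
}

#' Cliff's delta with 95% confidence interval
#'
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x * n_y)`. The interval
#' uses the consistent (unpooled) variance estimate
#' `var(d_i.)/n_x + var(d_.j)/n_y` — the sample variances of the row and
#' column means of the dominance matrix — with normal quantiles, clamped to
#' `[-1, 1]`.
#'
#' @param x,y Numeric value vectors.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `delta`, `ci_low`, `ci_high`.
#' @export
cliffs_delta <- function(x, y, conf_level = 0.95) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) stop("both groups must be non-empty")
  d_mat <- sign(outer(x, y, "-"))
  delta <- mean(d_mat)
  di <- rowMeans(d_mat)
  dj <- colMeans(d_mat)
  var_d <- 0
  if (nx > 1L) var_d <- var_d + stats::var(di) / nx
  if (ny > 1L) var_d <- var_d + stats::var(dj) / ny
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(var_d)
  if (nx == 1L && ny == 1L) half <- 2  # no variance information
  list(delta = delta,
       ci_low = max(-1, delta - half),
       ci_high = min(1, delta + half))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Sum of hypergeometric probabilities of tables (margins fixed) no more
#' probable than the observed one, via [stats::fisher.test()].
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("cells must be non-negative integers")
  }
  if (sum(table) == 0L) stop("all-zero table")
  stats::fisher.test(table)$p.value
}

#' Per-feature rank-based group comparison
#'
#' Runs [wmw_test()] and [cliffs_delta()] for every feature (column) of a
#' samples x features matrix between two groups, optionally adding
#' Benjamini-Hochberg adjusted q-values. Output rows are sorted by
#' descending Cliff's delta. Features constant across both groups get
#' `p = 1`, `delta = 0`.
#'
#' @param matrix Samples x features numeric matrix.
#' @param groups Two-level group labels, one per sample (row). The delta
#'   sign is for the second level versus the first (levels sorted,
#'   `"control"` first when present).
#' @param adjust Add BH-adjusted `fdr_q` across features?
#' @return `data.frame` with `feature_id`, `n_x`, `n_y`, `p_value`,
#'   `delta`, `delta_ci_low`, `delta_ci_high` (and `fdr_q`).
#' @export
compare_features <- function(matrix, groups, adjust = TRUE) {
  lev <- sort(unique(as.character(groups)))
  if (length(lev) != 2L) stop("groups must have exactly 2 levels")
  if ("control" %in% lev) lev <- c("control", setdiff(lev, "control"))
  ix <- groups == lev[1L]
  iy <- groups == lev[2L]
  res <- lapply(colnames(matrix), function(f) {
    x <- matrix[ix, f]; y <- matrix[iy, f]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(unique(c(x, y))) <= 1L) {
      return(data.frame(feature_id = f, n_x = length(x), n_y = length(y),
                        p_value = 1, delta = 0, delta_ci_low = 0,
                        delta_ci_high = 0, stringsAsFactors = FALSE))
    }
    cd <- cliffs_delta(y, x)  # effect of second level vs first
    data.frame(feature_id = f, n_x = length(x), n_y = length(y),
               p_value = wmw_test(x, y), delta = cd$delta,
               delta_ci_low = cd$ci_low, delta_ci_high = cd$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (adjust) out$fdr_q <- stats::p.adjust(out$p_value, "BH")
  out <- out[order(-out$delta), ]
  rownames(out) <- NULL
  out
}

#' Competitive taxon set enrichment
#'
#' For each named taxon set, compares the Cliff's delta values of member
#' features against non-members with a two-sided Wilcoxon-Mann-Whitney
#' rank test; p-values are BH-adjusted across sets. Sets with fewer than
#' two present members, or with no complement, are skipped with a warning.
#'
#' @param results Output of [compare_features()].
#' @param sets Named list of character vectors of feature IDs.
#' @return `data.frame` with `set`, `n_members`, `p_value`, `fdr_q`.
#' @export
taxon_set_enrichment <- function(results, sets) {
  rows <- list()
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], results$feature_id)
    if (length(members) < 2L) {
      warning("set '", nm, "' has fewer than 2 present members; skipped")
      next
    }
    inset <- results$feature_id %in% members
    if (all(inset)) {
      warning("set '", nm, "' covers all features (no complement); skipped")
      next
    }
    rows[[nm]] <- data.frame(
      set = nm, n_members = length(members),
      p_value = wmw_test(results$delta[inset], results$delta[!inset]),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(set = character(), n_members = integer(),
                      p_value = numeric(), fdr_q = numeric()))
  }
  out <- do.call(rbind, rows)
  out$fdr_q <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}
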