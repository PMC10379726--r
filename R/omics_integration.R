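# Interdomain (KO x metabolite) association analysis: pairwise Kendall
# correlation with matrix-wide BH control, treatment associations, ordinal
# FCT associations, and Ward/Euclidean heatmap ordering.

#' Kendall rank correlation (tau-b) with two-sided p-value
#'
#' Tau-b with tie correction via [stats::cor.test()]; exact p by
#' enumeration for n <= 8 without ties, normal approximation otherwise.
#' A constant vector yields tau = 0 with p = 1 and a warning.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return List with `tau` and `p`.
#' @export
kendall_tau <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("constant vector; tau undefined, returning 0 with p = 1")
    return(list(tau = 0, p = 1))
  }
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  use_exact <- !ties && length(x) <= 8L
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = use_exact))
  list(tau = unname(ct$estimate), p = ct$p.value)
}

#' Interdomain KO-metabolite Kendall correlation matrix
#'
#' Filters out features detected (value > 0) in fewer than `min_detect`
#' samples, computes all pairwise Kendall tau/p between the remaining KO
#' and metabolite features on row-aligned samples, and applies
#' Benjamini-Hochberg adjustment once across every cell of the matrix.
#' Significance is declared at FDR < `fdr` (default 10%).
#'
#' @param ko Samples x KOs abundance matrix.
#' @param mtb Samples x metabolites concentration matrix.
#' @param min_detect Minimum number of samples with detection (default 3).
#' @param fdr FDR threshold (default 0.10).
#' @return A list of class `correlation_matrix` with matrices `tau`, `p`,
#'   `q`, `significant` (KOs in rows, metabolites in columns) and the
#'   filtered feature names.
#' @export
interdomain_matrix <- function(ko, mtb, min_detect = 3L, fdr = 0.10) {
  shared <- intersect(rownames(ko), rownames(mtb))
  if (length(shared) == 0L) stop("no overlapping samples between tables")
  ko <- ko[shared, , drop = FALSE]
  mtb <- mtb[shared, , drop = FALSE]
  detected <- function(m) colSums(m > 0, na.rm = TRUE) >= min_detect
  keep_ko <- detected(ko); keep_mtb <- detected(mtb)
  ko <- ko[, keep_ko, drop = FALSE]
  mtb <- mtb[, keep_mtb, drop = FALSE]
  if (ncol(ko) == 0L || ncol(mtb) == 0L) {
    stop("no features left after the detection filter")
  }
  tau <- matrix(NA_real_, ncol(ko), ncol(mtb),
                dimnames = list(colnames(ko), colnames(mtb)))
  p <- tau
  for (i in seq_len(ncol(ko))) {
    for (j in seq_len(ncol(mtb))) {
      kt <- suppressWarnings(kendall_tau(ko[, i], mtb[, j]))
      tau[i, j] <- kt$tau
      p[i, j] <- kt$p
    }
  }
  q <- matrix(stats::p.adjust(as.vector(p), "BH"), nrow(p), ncol(p),
              dimnames = dimnames(p))
  structure(list(tau = tau, p = p, q = q, significant = q < fdr,
                 fdr = fdr, n_samples = length(shared),
                 dropped_ko = names(keep_ko)[!keep_ko],
                 dropped_mtb = names(keep_mtb)[!keep_mtb]),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d KOs x %d metabolites over %d samples; %d significant at FDR < %.0f%%\n",
              nrow(x$tau), ncol(x$tau), x$n_samples,
              sum(x$significant), 100 * x$fdr))
  invisible(x)
}

#' Treatment association of features at one visit
#'
#' Per-feature two-sided Mann-Whitney U test plus Cliff's delta between
#' arms among samples of one visit, BH-adjusted across features within the
#' visit. Reuses the [compare_features()] engine.
#'
#' @param features Samples x features matrix.
#' @param metadata Sample table with `sample_id`, `visit`, `arm`.
#' @param visit Visit label to restrict to (`NULL` = all samples).
#' @return [compare_features()] output with `fdr_q`.
#' @export
treatment_association <- function(features, metadata, visit = NULL) {
  meta <- metadata[match(rownames(features), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) stop("feature rows missing from metadata")
  keep <- if (is.null(visit)) rep(TRUE, nrow(meta)) else meta$visit == visit
  if (length(unique(meta$arm[keep])) != 2L) {
    stop("both arms must be present at the selected visit")
  }
  compare_features(features[keep, , drop = FALSE], meta$arm[keep],
                   adjust = TRUE)
}

#' Ordinal association between a feature and FCT labels
#'
#' Kendall correlation of a feature with the FCT label encoded as an
#' ordered integer (FCT1 = 1, FCT2 = 2, ...). A single observed FCT level
#' yields tau = 0, p = 1 with a warning.
#'
#' @param feature Numeric feature values.
#' @param fct_labels Integer (or ordered factor) FCT labels, aligned.
#' @return List with `tau` and `p`.
#' @export
fct_ordinal_association <- function(feature, fct_labels) {
  codes <- if (is.factor(fct_labels)) as.integer(fct_labels) else
    as.integer(fct_labels)
  if (length(unique(codes[!is.na(feature)])) < 2L) {
    warning("single FCT level present; tau undefined, returning 0 with p = 1")
    return(list(tau = 0, p = 1))
  }
  kendall_tau(feature, codes)
}

#' Heatmap leaf order by Ward clustering of correlation rows/columns
#'
#' Agglomerative Ward linkage (Ward.D2: squared Euclidean distances inside
#' the criterion) on Euclidean distances between tau row-vectors and
#' column-vectors of a [interdomain_matrix()] result.
#'
#' @param cm A `correlation_matrix` (or a plain tau matrix).
#' @return List with `row_order` and `col_order` (leaf orders), plus the
#'   `hclust` objects.
#' @export
cluster_heatmap_order <- function(cm) {
  tau <- if (inherits(cm, "correlation_matrix")) cm$tau else as.matrix(cm)
  row_order <- seq_len(nrow(tau)); col_order <- seq_len(ncol(tau))
  hr <- hc <- NULL
  if (nrow(tau) >= 2L) {
    hr <- stats::hclust(stats::dist(tau), method = "ward.D2")
    row_order <- hr$order
  }
  if (ncol(tau) >= 2L) {
    hc <- stats::hclust(stats::dist(t(tau)), method = "ward.D2")
    col_order <- hc$order
  }
  list(row_order = row_order, col_order = col_order,
       row_hclust = hr, col_hclust = hc)
}
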