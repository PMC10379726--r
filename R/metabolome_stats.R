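# Metabolome statistics: NIPALS PLS/PLS-DA, VIP scores, p(corr),
# cross-validated Q2Y with permutation testing, the discriminant-metabolite
# selection rule, bile-acid conjugation ratios and within-arm baseline-shift
# tests.

#' Fit a PLS model by NIPALS
#'
#' PLS2 regression of a response matrix `Y` (e.g. age in days plus a coded
#' treatment column, control = 0 / test = 1) on a metabolite matrix `X`.
#' Both are mean-centered; `X` columns are additionally scaled to unit
#' variance (default), Pareto-scaled, or left unscaled. `X` and `Y` are
#' deflated after each component. Constant `X` columns are dropped with a
#' warning.
#'
#' @param X Samples x variables numeric matrix.
#' @param Y Samples x responses numeric matrix (or vector).
#' @param n_components Number of latent components.
#' @param scaling `"unit_variance"`, `"pareto"`, or `"none"`.
#' @return A list of class `pls_model` with per-component `x_scores` (T),
#'   `x_weights` (W, unit norm), `x_loadings` (P), `y_loadings` (Q),
#'   `explained_y_variance` (fractions of the total centered Y sum of
#'   squares), the preprocessing parameters, and the scaled `X` matrix.
#' @export
fit_pls <- function(X, Y, n_components = 2L,
                    scaling = c("unit_variance", "pareto", "none")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must be row-aligned")
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))

  sds <- apply(X, 2L, stats::sd)
  if (scaling != "none" && any(sds == 0)) {
    warning(sum(sds == 0), " constant X column(s) dropped: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  x_mean <- colMeans(X)
  x_scale <- switch(scaling, unit_variance = sds, pareto = sqrt(sds),
                    none = rep(1, ncol(X)))
  Xs <- sweep(sweep(X, 2L, x_mean), 2L, x_scale, "/")
  y_mean <- colMeans(Y)
  Ys <- sweep(Y, 2L, y_mean)
  ssy_total <- sum(Ys^2)
  if (ssy_total == 0) stop("Y has no variance")

  n <- nrow(Xs); p <- ncol(Xs); q <- ncol(Ys)
  A <- min(n_components, p, n - 1L)
  W <- matrix(0, p, A, dimnames = list(colnames(Xs), NULL))
  P <- matrix(0, p, A, dimnames = list(colnames(Xs), NULL))
  Tm <- matrix(0, n, A, dimnames = list(rownames(X), NULL))
  Q <- matrix(0, q, A, dimnames = list(colnames(Y), NULL))
  ssy <- numeric(A)
  Xd <- Xs; Yd <- Ys
  for (a in seq_len(A)) {
    u <- Yd[, which.max(apply(Yd, 2L, stats::var))]
    if (all(u == 0)) break
    t_old <- rep(0, n)
    for (it in seq_len(500L)) {
      w <- crossprod(Xd, u)[, 1L]
      w <- w / sqrt(sum(w^2))
      t_sc <- Xd %*% w
      qv <- crossprod(Yd, t_sc)[, 1L] / sum(t_sc^2)
      if (q == 1L) break
      u <- (Yd %*% qv) / sum(qv^2)
      if (sqrt(sum((t_sc - t_old)^2)) < 1e-12 * sqrt(sum(t_sc^2))) break
      t_old <- t_sc
    }
    p_load <- crossprod(Xd, t_sc)[, 1L] / sum(t_sc^2)
    W[, a] <- w; Tm[, a] <- t_sc; P[, a] <- p_load; Q[, a] <- qv
    ssy[a] <- sum(t_sc^2) * sum(qv^2)
    Xd <- Xd - tcrossprod(t_sc, p_load)
    Yd <- Yd - tcrossprod(t_sc, qv)
  }
  structure(list(n_components = A, x_scores = Tm, x_weights = W,
                 x_loadings = P, y_loadings = Q,
                 explained_y_variance = ssy / ssy_total,
                 scaling = scaling, centering = TRUE,
                 x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
                 X_scaled = Xs),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), R2Y = %.3f (per component: %s)\n",
              x$n_components, sum(x$explained_y_variance),
              paste(sprintf("%.3f", x$explained_y_variance), collapse = ", ")))
  invisible(x)
}

# Predict responses for new data from a fitted PLS model.
predict_pls <- function(model, X_new) {
  X_new <- as.matrix(X_new)[, names(model$x_mean), drop = FALSE]
  Xs <- sweep(sweep(X_new, 2L, model$x_mean), 2L, model$x_scale, "/")
  B <- model$x_weights %*%
    solve(crossprod(model$x_loadings, model$x_weights)) %*% t(model$y_loadings)
  sweep(Xs %*% B, 2L, model$y_mean, "+")
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a SSY_a * (w_ja / ||w_a||)^2 / sum_a SSY_a)`:
#' the weighted sum of squares of the PLS weights, weighting each
#' component by its explained Y-variance. Satisfies
#' `sum(VIP^2) = p` (number of X variables).
#'
#' @param model A fitted `pls_model`.
#' @return Named vector of VIP scores.
#' @export
vip <- function(model) {
  ssy <- model$explained_y_variance
  if (sum(ssy) <= 0) stop("model explains no Y variance")
  W <- model$x_weights
  wn2 <- sweep(W^2, 2L, colSums(W^2), "/")
  p <- nrow(W)
  stats::setNames(sqrt(p * as.numeric(wn2 %*% ssy) / sum(ssy)), rownames(W))
}

#' Correlation of variables with a component's scores (p(corr))
#'
#' Pearson correlation between the chosen component's score vector and each
#' scaled X column. Constant columns get 0 with a warning.
#'
#' @param model A fitted `pls_model`.
#' @param component Component index (e.g. 2 for the treatment component of
#'   a combined age + treatment model).
#' @param X Optional data matrix; defaults to the training data.
#' @return Named vector of correlations in `[-1, 1]`.
#' @export
p_corr <- function(model, component = 1L, X = NULL) {
  if (component > model$n_components) stop("component index out of range")
  t_sc <- model$x_scores[, component]
  Xs <- if (is.null(X)) {
    model$X_scaled
  } else {
    X <- as.matrix(X)[, names(model$x_mean), drop = FALSE]
    sweep(sweep(X, 2L, model$x_mean), 2L, model$x_scale, "/")
  }
  out <- suppressWarnings(as.numeric(stats::cor(Xs, t_sc)))
  names(out) <- colnames(Xs)
  if (anyNA(out)) {
    warning("constant column(s); correlation set to 0: ",
            paste(names(out)[is.na(out)], collapse = ", "))
    out[is.na(out)] <- 0
  }
  out
}

#' Cross-validated Q2Y and permutation test for a PLS model
#'
#' Q2Y = 1 - PRESS/SS over venetian-blind folds (fold membership cycles
#' through the sample order after a seeded shuffle), averaged across Y
#' columns. The permutation p-value is the fraction of Y-row-permuted
#' refits achieving Q2 at least as high as observed, with the +1
#' correction `p = (1 + #better) / (n_permutations + 1)`.
#'
#' @inheritParams fit_pls
#' @param folds Number of cross-validation folds (default 7).
#' @param n_permutations Number of Y permutations (0 = Q2 only).
#' @param seed Integer seed for fold assignment and permutations.
#' @return List with `q2y` and `permutation_p` (NA when not computed).
#' @export
validate_pls <- function(X, Y, n_components = 2L, folds = 7L,
                         n_permutations = 200L, seed = 1L,
                         scaling = "unit_variance") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (folds < 2L) stop("need at least 2 folds")
  fold_id <- with_seed(child_seed(seed, "folds"), {
    ord <- sample.int(n)
    id <- integer(n)
    id[ord] <- (seq_len(n) - 1L) %% folds + 1L
    id
  })
  q2 <- function(Yv) {
    press <- matrix(0, 1L, ncol(Yv)); ss <- matrix(0, 1L, ncol(Yv))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      m <- fit_pls(X[tr, , drop = FALSE], Yv[tr, , drop = FALSE],
                   n_components, scaling)
      pred <- predict_pls(m, X[!tr, , drop = FALSE])
      press <- press + colSums((Yv[!tr, , drop = FALSE] - pred)^2)
      ctr <- matrix(m$y_mean, sum(!tr), ncol(Yv), byrow = TRUE)
      ss <- ss + colSums((Yv[!tr, , drop = FALSE] - ctr)^2)
    }
    mean(1 - press / ss)
  }
  q2y_obs <- suppressWarnings(q2(Y))
  perm_p <- NA_real_
  if (n_permutations > 0L) {
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      Yp <- with_seed(child_seed(seed, paste0("perm", b)),
                      Y[sample.int(n), , drop = FALSE])
      if (suppressWarnings(q2(Yp)) >= q2y_obs) hits <- hits + 1L
    }
    perm_p <- (1 + hits) / (n_permutations + 1)
  }
  list(q2y = q2y_obs, permutation_p = perm_p)
}

#' Discriminant-metabolite selection rule
#'
#' A metabolite is selected as discriminating the treatment groups when
#' VIP > 1, |p(corr)| > 0.2 and the univariate WMW p-value < 0.05.
#' Metabolites missing any statistic are excluded with a warning. The
#' output is sorted by descending VIP.
#'
#' @param vips,p_corrs,wmw_ps Aligned named vectors (or vectors plus
#'   `ids`).
#' @param ids Metabolite identifiers (defaults to `names(vips)`).
#' @return `data.frame` with `metabolite_id`, `vip`, `p_corr`, `wmw_p`,
#'   `selected`.
#' @export
select_discriminant <- function(vips, p_corrs, wmw_ps, ids = names(vips)) {
  if (is.null(ids)) ids <- sprintf("m%d", seq_along(vips))
  df <- data.frame(metabolite_id = ids, vip = as.numeric(vips),
                   p_corr = as.numeric(p_corrs), wmw_p = as.numeric(wmw_ps),
                   stringsAsFactors = FALSE)
  bad <- !stats::complete.cases(df)
  if (any(bad)) {
    warning(sum(bad), " metabolite(s) missing a statistic excluded: ",
            paste(df$metabolite_id[bad], collapse = ", "))
    df <- df[!bad, ]
  }
  df$selected <- df$vip > 1 & abs(df$p_corr) > 0.2 & df$wmw_p < 0.05
  df <- df[order(-df$vip), ]
  rownames(df) <- NULL
  df
}

#' Unconjugated/conjugated bile-acid ratios
#'
#' Markers of bacterial bile salt hydrolase activity:
#' * `ba_cba` — total ratio `(CA + CDCA + LCA + DCA) /
#'   (TCA + TCDCA + TDCA + GCA + TLCA + GCDCA + GDCA)`;
#' * `ca_cca` — `CA / (GCA + TCA)`;
#' * `cdca_ccdca` — `CDCA / (GCDCA + TCDCA)`;
#' * `lca_clca` — `LCA / (GLCA + TLCA)`.
#'
#' A zero or missing conjugated denominator yields `NA` (undefined), never
#' infinity.
#'
#' @param panel Named numeric vector of bile-acid concentrations for one
#'   sample, or a samples x analytes matrix.
#' @return `data.frame` with columns `ba_cba`, `ca_cca`, `cdca_ccdca`,
#'   `lca_clca` (one row per sample).
#' @export
bile_acid_ratios <- function(panel) {
  if (is.null(dim(panel))) panel <- matrix(panel, nrow = 1L,
                                           dimnames = list("s", names(panel)))
  get <- function(nms) {
    miss <- setdiff(nms, colnames(panel))
    if (length(miss)) return(rep(NA_real_, nrow(panel)))
    rowSums(panel[, nms, drop = FALSE])
  }
  ratio <- function(num, den) ifelse(is.na(den) | den <= 0, NA_real_,
                                     num / den)
  data.frame(
    ba_cba = ratio(get(c("CA", "CDCA", "LCA", "DCA")),
                   get(c("TCA", "TCDCA", "TDCA", "GCA", "TLCA", "GCDCA",
                         "GDCA"))),
    ca_cca = ratio(get("CA"), get(c("GCA", "TCA"))),
    cdca_ccdca = ratio(get("CDCA"), get(c("GCDCA", "TCDCA"))),
    lca_clca = ratio(get("LCA"), get(c("GLCA", "TLCA"))),
    row.names = rownames(panel))
}

#' Within-arm baseline-shift tests
#'
#' Two-sided unpaired WMW tests of a metabolite (or ratio) at each
#' post-baseline visit (V1, V3, V6) against baseline (V0), within one arm.
#' Visits without samples are skipped with a warning.
#'
#' @param values Named numeric vector (names are sample IDs) or a vector
#'   aligned with `metadata` rows.
#' @param metadata Sample table with `sample_id`, `visit`, `arm`.
#' @param arm Arm to test within (`"control"` or `"test"`).
#' @return Named vector of p-values for V1, V3, V6 (`NA` when skipped).
#' @export
baseline_shift_tests <- function(values, metadata, arm) {
  if (!is.null(names(values))) {
    values <- values[match(metadata$sample_id, names(values))]
  }
  sel <- metadata$arm == arm & !is.na(values)
  v0 <- values[sel & metadata$visit == "V0"]
  out <- c(V1 = NA_real_, V3 = NA_real_, V6 = NA_real_)
  if (length(v0) == 0L) {
    warning("no baseline (V0) samples in arm '", arm, "'")
    return(out)
  }
  for (v in names(out)) {
    vv <- values[sel & metadata$visit == v]
    if (length(vv) == 0L) {
      warning("no ", v, " samples in arm '", arm, "'; skipped")
      next
    }
    out[v] <- wmw_test(vv, v0)
  }
  out
}
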