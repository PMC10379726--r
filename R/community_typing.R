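# Dirichlet multinomial mixture (DMM) community typing.
#
# Samples are genus-level count vectors; each mixture component k has a
# positive Dirichlet parameter vector alpha_k and mixture weight pi_k. The
# model is fitted by EM: E-step responsibilities proportional to
# pi_k * DM(x; alpha_k); M-step updates pi_k and the responsibility-weighted
# alpha_k by the digamma-ratio fixed point (an MM update, so the
# observed-data log-likelihood is non-decreasing). The number of components
# is chosen by the minimal Laplace-approximated negative log model
# evidence, the selected components are labelled fecal community types
# (FCTs) and renumbered by temporal appearance.

#' Dirichlet-multinomial log pmf
#'
#' `log[n!/prod(x_j!)] + lgamma(A) - lgamma(n+A) +
#'  sum_j (lgamma(x_j + a_j) - lgamma(a_j))` with `A = sum(a)`.
#'
#' @param counts Non-negative integer vector.
#' @param alpha Positive parameter vector of the same length.
#' @return Log probability mass.
#' @export
dm_log_pmf <- function(counts, alpha) {
  if (length(counts) != length(alpha)) stop("lengths of counts and alpha differ")
  if (any(counts < 0)) stop("negative counts")
  if (any(alpha <= 0)) stop("alpha must be positive")
  n <- sum(counts)
  A <- sum(alpha)
  lgamma(n + 1) - sum(lgamma(counts + 1)) +
    lgamma(A) - lgamma(n + A) +
    sum(lgamma(counts + alpha) - lgamma(alpha))
}

# Vectorised component log-likelihood: log DM(x_i; alpha) for every row of
# X, sharing the precomputed log multinomial coefficient `lmc` and row sums
# `n_i`.
dm_loglik_rows <- function(X, alpha, lmc, n_i) {
  A <- sum(alpha)
  lmc + lgamma(A) - lgamma(n_i + A) +
    rowSums(lgamma(sweep(X, 2L, alpha, "+"))) - sum(lgamma(alpha))
}

# One or more digamma-ratio fixed-point updates of a responsibility-weighted
# Dirichlet-multinomial MLE (Minka's bound; each pass increases the weighted
# likelihood).
update_alpha <- function(alpha, X, r, n_i, inner = 5L, floor_a = 1e-8) {
  for (it in seq_len(inner)) {
    A <- sum(alpha)
    den <- sum(r * (digamma(n_i + A) - digamma(A)))
    if (!is.finite(den) || den <= 0) break
    num <- as.numeric(crossprod(r, digamma(sweep(X, 2L, alpha, "+")))) -
      sum(r) * digamma(alpha)
    alpha <- pmax(alpha * num / den, floor_a)
  }
  alpha
}

# Centered-log-ratio transform with pseudocount, for initialisation only.
clr_counts <- function(X, pseudocount = 0.5) {
  P <- (X + pseudocount) / rowSums(X + pseudocount)
  L <- log(P)
  L - rowMeans(L)
}

# k-means++ seeding followed by a short k-means run; returns hard labels.
kmeanspp_labels <- function(Z, K) {
  n <- nrow(Z)
  centers <- matrix(NA_real_, K, ncol(Z))
  centers[1L, ] <- Z[sample.int(n, 1L), ]
  d2 <- rowSums((Z - matrix(centers[1L, ], n, ncol(Z), byrow = TRUE))^2)
  if (K > 1L) {
    for (k in 2L:K) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[k, ] <- Z[sample.int(n, 1L, prob = p), ]
      d2 <- pmin(d2, rowSums((Z - matrix(centers[k, ], n, ncol(Z),
                                         byrow = TRUE))^2))
    }
  }
  centers <- centers[!duplicated(centers), , drop = FALSE]
  km <- suppressWarnings(stats::kmeans(Z, centers, iter.max = 25L))
  km$cluster
}

#' Fit a Dirichlet multinomial mixture by EM
#'
#' @param counts Samples x taxa integer matrix (non-rarefied genus counts).
#' @param K Number of mixture components.
#' @param restarts Number of independently initialised EM runs; the run
#'   with the lowest Laplace negative log evidence is kept.
#' @param tol Relative change in observed-data log-likelihood declaring
#'   convergence.
#' @param max_iter Maximum EM iterations per run.
#' @param inner_iter Fixed-point passes per M-step alpha update.
#' @param seed Integer seed (restarts derive distinct child seeds).
#' @return An object of class `dmm_model`: `K`, `alpha` (K x taxa),
#'   `weights`, `responsibilities`, `log_lik`, `log_lik_trace`,
#'   `neg_log_evidence`, `converged`, `iterations`, `fit_meta`.
#' @export
fit_dmm <- function(counts, K, restarts = 1L, tol = 1e-6, max_iter = 500L,
                    inner_iter = 5L, seed = 1L) {
  X <- as.matrix(counts)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (K < 1L) stop("K must be at least 1")
  if (n < K) stop("need at least K samples")
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_seed(child_seed(seed, paste0("dmm", K, "r", r)),
                     fit_dmm_once(X, K, tol, max_iter, inner_iter))
    fit$neg_log_evidence <- laplace_neg_log_evidence(fit, X)
    if (is.null(best) || fit$neg_log_evidence < best$neg_log_evidence) {
      best <- fit
    }
  }
  best$fit_meta <- list(seed = seed, restarts = restarts, tol = tol,
                        max_iter = max_iter, inner_iter = inner_iter)
  best
}

fit_dmm_once <- function(X, K, tol, max_iter, inner_iter) {
  n <- nrow(X)
  Tn <- ncol(X)
  n_i <- rowSums(X)
  lmc <- lgamma(n_i + 1) - rowSums(lgamma(X + 1))

  # initialise from a k-means++ partition of clr-transformed proportions
  z <- if (K == 1L) rep(1L, n) else kmeanspp_labels(clr_counts(X), K)
  K_eff <- max(z)
  R <- matrix(0.05 / K_eff, n, K_eff)
  R[cbind(seq_len(n), z)] <- R[cbind(seq_len(n), z)] + 0.95
  R <- R / rowSums(R)
  w <- colMeans(R)
  P <- (X + 0.5) / rowSums(X + 0.5)
  alpha <- matrix(0, K_eff, Tn, dimnames = list(NULL, colnames(X)))
  for (k in seq_len(K_eff)) {
    alpha[k, ] <- pmax(crossprod(R[, k], P) / sum(R[, k]), 1e-6) * 30
  }

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  pruned <- FALSE
  repeat {
    iter <- iter + 1L
    K_cur <- nrow(alpha)
    L <- matrix(0, n, K_cur)
    for (k in seq_len(K_cur)) {
      L[, k] <- dm_loglik_rows(X, alpha[k, ], lmc, n_i)
    }
    Lw <- sweep(L, 2L, log(w), "+")
    mx <- Lw[cbind(seq_len(n), max.col(Lw, ties.method = "first"))]
    ll <- sum(mx + log(rowSums(exp(Lw - mx))))
    ll_trace <- c(ll_trace, ll)
    R <- exp(Lw - mx)
    R <- R / rowSums(R)

    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * max(1, abs(ll_prev))) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- ll

    w <- colMeans(R)
    dead <- w < 1e-8
    if (any(dead)) {
      warning("pruning ", sum(dead), " degenerate component(s) with weight < 1e-8")
      pruned <- TRUE
      keep <- !dead
      w <- w[keep] / sum(w[keep])
      alpha <- alpha[keep, , drop = FALSE]
      R <- R[, keep, drop = FALSE]
      R <- R / rowSums(R)
      next
    }
    for (k in seq_len(K_cur)) {
      alpha[k, ] <- update_alpha(alpha[k, ], X, R[, k], n_i, inner_iter)
    }
  }

  rownames(R) <- rownames(X)
  structure(list(K = nrow(alpha), K_requested = K, alpha = alpha,
                 weights = w, responsibilities = R, log_lik = ll,
                 log_lik_trace = ll_trace, converged = converged,
                 iterations = iter, pruned = pruned),
            class = "dmm_model")
}

#' @export
print.dmm_model <- function(x, ...) {
  cat(sprintf("<dmm_model> K = %d, log-lik = %.2f, -log evidence = %.2f (%s after %d EM iterations)\n",
              x$K, x$log_lik,
              if (is.null(x$neg_log_evidence)) NA else x$neg_log_evidence,
              if (x$converged) "converged" else "not converged", x$iterations))
  invisible(x)
}

#' Laplace-approximated negative log model evidence of a DMM
#'
#' The evidence is approximated at the fitted mode in log-alpha space with
#' a weak Gaussian prior on `log(alpha)` (sd 10). The Hessian of the
#' negative log posterior is analytic and block-diagonal per component
#' (responsibility-weighted); the mixture weights contribute a
#' `((K-1)/2) log n` dimensionality term. Components whose Hessian block is
#' not positive definite fall back to a BIC-style penalty with a warning.
#'
#' @param model A fitted `dmm_model`.
#' @param counts The count matrix the model was fitted to.
#' @return The negative log evidence (lower is better).
#' @export
laplace_neg_log_evidence <- function(model, counts) {
  X <- as.matrix(counts)
  storage.mode(X) <- "double"
  n <- nrow(X)
  Tn <- ncol(X)
  n_i <- rowSums(X)
  prior_sd <- 10
  log_prior <- 0
  half_logdet <- 0
  for (k in seq_len(model$K)) {
    a <- model$alpha[k, ]
    r <- model$responsibilities[, k]
    lam <- log(a)
    log_prior <- log_prior + sum(stats::dnorm(lam, 0, prior_sd, log = TRUE))
    A <- sum(a)
    Xa <- sweep(X, 2L, a, "+")
    # derivatives of the weighted DM log-likelihood w.r.t. alpha
    g_alpha <- as.numeric(crossprod(r, digamma(Xa))) - sum(r) * digamma(a) +
      sum(r * (digamma(A) - digamma(n_i + A)))
    c0 <- sum(r * (trigamma(A) - trigamma(n_i + A)))
    D <- as.numeric(crossprod(r, trigamma(Xa))) - sum(r) * trigamma(a)
    # Hessian in lambda = log(alpha) space
    H_ll <- tcrossprod(a) * c0 + diag(a^2 * D + a * g_alpha, Tn)
    H <- -H_ll + diag(1 / prior_sd^2, Tn)
    ev <- tryCatch(determinant(H, logarithm = TRUE), error = function(e) NULL)
    pd <- !is.null(ev) && ev$sign > 0 &&
      all(diag(H) > 0)
    if (pd) {
      half_logdet <- half_logdet + 0.5 * as.numeric(ev$modulus)
    } else {
      warning("non-positive-definite Hessian block for component ", k,
              "; BIC-style fallback")
      half_logdet <- half_logdet + 0.5 * Tn * log(max(sum(r), 2))
    }
  }
  d_alpha <- model$K * Tn
  log_evidence <- model$log_lik + log_prior +
    0.5 * d_alpha * log(2 * pi) - half_logdet -
    0.5 * (model$K - 1) * log(n)
  -log_evidence
}

#' Select the number of DMM components by minimal Laplace evidence
#'
#' Fits DMMs across `K_range` with `repeats` restarts each and returns the
#' fit minimising the Laplace negative log model evidence (ties broken
#' toward smaller K). The evidence-vs-K table is attached as the
#' `"evidence_table"` attribute.
#'
#' @inheritParams fit_dmm
#' @param K_range Integer vector of candidate component numbers.
#' @param repeats Restarts per K.
#' @return The best `dmm_model`.
#' @export
select_dmm <- function(counts, K_range = 2:10, repeats = 10L, tol = 1e-6,
                       max_iter = 500L, seed = 1L) {
  if (length(K_range) == 0L) stop("K_range is empty")
  fits <- list()
  errs <- character(0)
  for (K in sort(K_range)) {
    f <- tryCatch(
      fit_dmm(counts, K, restarts = repeats, tol = tol,
              max_iter = max_iter, seed = child_seed(seed, paste0("sel", K))),
      error = function(e) e)
    if (inherits(f, "error")) {
      errs <- c(errs, sprintf("K=%d: %s", K, conditionMessage(f)))
    } else {
      fits[[as.character(K)]] <- f
    }
  }
  if (length(fits) == 0L) {
    stop("all DMM fits failed:\n", paste(errs, collapse = "\n"))
  }
  tab <- data.frame(
    K = as.integer(names(fits)),
    K_effective = vapply(fits, function(f) f$K, 1L),
    neg_log_evidence = vapply(fits, function(f) f$neg_log_evidence, 1),
    log_lik = vapply(fits, function(f) f$log_lik, 1),
    converged = vapply(fits, function(f) f$converged, TRUE))
  rownames(tab) <- NULL
  best <- fits[[which.min(tab$neg_log_evidence)]]
  attr(best, "evidence_table") <- tab
  best
}

#' Hard sample-to-component assignment from a DMM
#'
#' Argmax of the responsibility rows; ties broken toward the lowest
#' component index.
#'
#' @param model A fitted `dmm_model`.
#' @param sample_ids Optional sample identifiers (defaults to the
#'   responsibility row names).
#' @return `data.frame` with `sample_id` and `fct` (raw component index).
#' @export
fct_assign <- function(model, sample_ids = rownames(model$responsibilities)) {
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%04d", seq_len(nrow(model$responsibilities)))
  }
  data.frame(sample_id = sample_ids,
             fct = max.col(model$responsibilities, ties.method = "first"),
             stringsAsFactors = FALSE)
}

#' Renumber community types by temporal appearance
#'
#' Components are renumbered by ascending mean age of their member samples
#' (FCT1 earliest), with ties broken by ascending median age and then by
#' the raw component index. The renumbering map is attached as the
#' `"fct_map"` attribute (`fct_map[raw]` = new label).
#'
#' @param assignment `data.frame` with `sample_id` and `fct` columns, as
#'   from [fct_assign()].
#' @param metadata Sample table with `sample_id` and `age` columns.
#' @return The assignment with renumbered `fct` labels.
#' @export
order_fcts <- function(assignment, metadata) {
  age <- metadata$age[match(assignment$sample_id, metadata$sample_id)]
  if (any(is.na(age))) stop("every assigned sample needs an age in metadata")
  comps <- sort(unique(assignment$fct))
  mean_age <- vapply(comps, function(k) mean(age[assignment$fct == k]), 1)
  med_age <- vapply(comps, function(k) stats::median(age[assignment$fct == k]), 1)
  ord <- order(mean_age, med_age, comps)
  if (anyDuplicated(mean_age)) {
    message("tie in component mean ages broken by median age, then raw index")
  }
  fct_map <- integer(max(comps))
  fct_map[comps[ord]] <- seq_along(comps)
  out <- assignment
  out$fct <- fct_map[assignment$fct]
  attr(out, "fct_map") <- fct_map
  out
}
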