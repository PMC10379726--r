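# FCT maturation trajectory: age-binned transition network and
# time-to-transition survival analysis.

DAYS_PER_MONTH <- 30.4375  # mean Gregorian month

#' Assign an age in days to a month bin
#'
#' `round(age / 30.4375)` with half-up rounding (0.5 always rounds up),
#' so 44 d -> month 1 and 75 d -> month 2.
#'
#' @param age Age in days (vectorised, non-negative).
#' @return Integer month index.
#' @export
assign_age_group <- function(age) {
  if (any(age < 0)) stop("negative age")
  as.integer(floor(age / DAYS_PER_MONTH + 0.5))
}

#' Build the age-binned FCT transition network
#'
#' Every consecutive pair of samples from the same infant contributes one
#' edge from its source month bin to its destination month bin. Pairs in
#' the same bin give self-loops; skipped bins are allowed (an edge may jump
#' from month i to any later month). Node occupancy is the fraction of an
#' age column's samples in each FCT; an edge's fraction is its count over
#' all transitions leaving its source age column. Edges are categorised as
#' `no_change`, `progression` (FCT increases) or `regression`, and edges at
#' or below `display_threshold` are flagged `hidden` (kept in the data,
#' excluded from rendering).
#'
#' @param assignment `data.frame` with `sample_id`, `fct`.
#' @param metadata Sample table with `sample_id`, `infant_id`, `age`.
#' @param display_threshold Minimum displayed edge fraction (default 0.04:
#'   only transitions with frequencies above 4% are shown).
#' @return A list of class `transition_graph` with `nodes`, `edges` and
#'   `display_threshold`.
#' @export
build_transition_graph <- function(assignment, metadata,
                                   display_threshold = 0.04) {
  df <- merge(assignment, metadata[, c("sample_id", "infant_id", "age")],
              by = "sample_id")
  df$month <- assign_age_group(df$age)
  df <- df[order(df$infant_id, df$age), ]

  nodes <- stats::aggregate(sample_id ~ month + fct, df, length)
  names(nodes)[3L] <- "n"
  col_tot <- stats::aggregate(n ~ month, nodes, sum)
  nodes$occupancy <- nodes$n / col_tot$n[match(nodes$month, col_tot$month)]
  nodes <- nodes[order(nodes$month, nodes$fct), ]
  rownames(nodes) <- NULL

  edge_rows <- list()
  for (inf in unique(df$infant_id)) {
    s <- df[df$infant_id == inf, ]
    if (nrow(s) < 2L) next  # single-sample infants contribute nodes only
    for (i in seq_len(nrow(s) - 1L)) {
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        from_month = s$month[i], from_fct = s$fct[i],
        to_month = s$month[i + 1L], to_fct = s$fct[i + 1L])
    }
  }
  if (length(edge_rows)) {
    e <- do.call(rbind, edge_rows)
    e$n <- 1L
    edges <- stats::aggregate(n ~ from_month + from_fct + to_month + to_fct,
                              e, sum)
    leaving <- stats::aggregate(n ~ from_month, edges, sum)
    edges$fraction <- edges$n /
      leaving$n[match(edges$from_month, leaving$from_month)]
    edges$category <- ifelse(edges$to_fct == edges$from_fct, "no_change",
                             ifelse(edges$to_fct > edges$from_fct,
                                    "progression", "regression"))
    edges$hidden <- edges$fraction <= display_threshold
    edges <- edges[order(edges$from_month, edges$from_fct, edges$to_month,
                         edges$to_fct), ]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from_month = integer(), from_fct = integer(),
                        to_month = integer(), to_fct = integer(),
                        n = integer(), fraction = numeric(),
                        category = character(), hidden = logical())
  }
  structure(list(nodes = nodes, edges = edges,
                 display_threshold = display_threshold),
            class = "transition_graph")
}

#' @export
print.transition_graph <- function(x, ...) {
  cat(sprintf("<transition_graph> %d nodes, %d edges (%d shown at threshold %.2f)\n",
              nrow(x$nodes), nrow(x$edges), sum(!x$edges$hidden),
              x$display_threshold))
  invisible(x)
}

#' Time-to-FCT survival records
#'
#' For each infant, the event time is the age at the earliest visit where
#' the infant is observed in `target_fct` or a later FCT; infants never
#' observed there are right-censored at their last visit age. Infants with
#' fewer than two samples are excluded with a message.
#'
#' @param assignment `data.frame` with `sample_id`, `fct`.
#' @param metadata Sample table with `sample_id`, `infant_id`, `age`, `arm`.
#' @param target_fct Target community type (event = reaching it or any
#'   later FCT).
#' @return `data.frame` with `infant_id`, `time` (days), `event`
#'   (0/1), `arm`.
#' @export
fct_event_table <- function(assignment, metadata, target_fct) {
  df <- merge(assignment,
              metadata[, c("sample_id", "infant_id", "age", "arm")],
              by = "sample_id")
  df <- df[order(df$infant_id, df$age), ]
  n_samp <- table(df$infant_id)
  few <- names(n_samp)[n_samp < 2L]
  if (length(few)) {
    message(length(few), " infant(s) with fewer than 2 samples excluded ",
            "from the survival analysis")
    df <- df[!df$infant_id %in% few, ]
  }
  if (nrow(df) == 0L) {
    warning("no infants left after exclusions")
    return(data.frame(infant_id = character(), time = numeric(),
                      event = integer(), arm = character()))
  }
  recs <- lapply(split(df, df$infant_id), function(s) {
    hit <- which(s$fct >= target_fct)
    if (length(hit)) {
      data.frame(infant_id = s$infant_id[1L], time = s$age[hit[1L]],
                 event = 1L, arm = s$arm[1L], stringsAsFactors = FALSE)
    } else {
      data.frame(infant_id = s$infant_id[1L], time = max(s$age),
                 event = 0L, arm = s$arm[1L], stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier product-limit curve
#'
#' @param records Survival records from [fct_event_table()] (columns
#'   `time`, `event`, optionally `arm` for stratified curves).
#' @param by_arm Stratify by arm?
#' @return `data.frame` with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` (and `arm` when stratified).
#' @export
km_curve <- function(records, by_arm = FALSE) {
  if (nrow(records) < 1L) stop("need at least one record")
  fit <- if (by_arm) {
    survival::survfit(survival::Surv(time, event) ~ arm, data = records)
  } else {
    survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  }
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  if (by_arm && !is.null(fit$strata)) {
    out$arm <- rep(sub("^arm=", "", names(fit$strata)), fit$strata)
  }
  out
}

#' Cox proportional hazards fit for a binary group
#'
#' Single binary covariate Cox model (Breslow tie handling) via
#' [survival::coxph()]. The hazard ratio is `exp(beta)` with a 95% Wald
#' interval; global significance is the score (log-rank) test. Under
#' complete separation the coefficient is capped at `|beta| <= 20` with a
#' warning.
#'
#' @param records Survival records (`time`, `event`).
#' @param group Two-level group labels aligned with `records` (defaults to
#'   `records$arm`); the hazard ratio is for the second level relative to
#'   the first, with levels sorted so `"control"` is the reference when
#'   present.
#' @return A list of class `cox_result`: `hazard_ratio`, `ci_low`,
#'   `ci_high`, `score_chi2`, `score_p`, `n`, `n_event`.
#' @export
cox_binary <- function(records, group = records$arm) {
  if (length(unique(group)) != 2L) stop("exactly two groups required")
  if (sum(records$event) < 1L) stop("no events observed")
  lev <- sort(unique(group))
  if ("control" %in% lev) lev <- c("control", setdiff(lev, "control"))
  g <- factor(group, levels = lev)
  dat <- data.frame(time = records$time, event = records$event, g = g)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ g, data = dat,
                    ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1L, 1L]))
  if (!is.finite(beta) || abs(beta) > 20) {
    warning("complete or near-complete separation; coefficient capped at |beta| = 20")
    beta <- sign(beta) * 20
  }
  sc <- summary(fit)$sctest
  structure(list(hazard_ratio = exp(beta),
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 score_chi2 = unname(sc["test"]),
                 score_p = unname(sc["pvalue"]),
                 n = nrow(records), n_event = sum(records$event)),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> HR = %.3f [%.3f, %.3f], score chi2 = %.3f, log-rank p = %.4g (%d events / %d)\n",
              x$hazard_ratio, x$ci_low, x$ci_high, x$score_chi2, x$score_p,
              x$n_event, x$n))
  invisible(x)
}
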