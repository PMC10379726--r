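# End-to-end pipeline orchestration: simulate (or load) -> rarefy/diversity
# -> community typing -> trajectory/survival -> differential abundance ->
# metabolome -> interdomain integration, with a machine-readable results
# bundle. The R functions are the programmatic interface; this module wires
# them together from a single flat configuration.

#' Read a flat key-value pipeline configuration
#'
#' TOML-style syntax restricted to `[section]` headers, `key = value` pairs
#' and `#` comments. Values are parsed as numbers when possible, otherwise
#' kept as strings; section names prefix the keys (`section.key`).
#'
#' @param path Path to the configuration file.
#' @return Named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("cannot parse config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) val <- num
    name <- if (nzchar(section)) paste(section, key, sep = ".") else key
    out[[name]] <- val
  }
  out
}

#' Run the full longitudinal analysis
#'
#' Orchestrates every stage on a synthetic or user-supplied cohort and
#' writes a results bundle (TSV/JSON files plus a run manifest) to
#' `out_dir`. Stages: rarefied Faith's PD per sample, DMM community typing
#' with K selection, FCT ordering, transition graph, time-to-FCT3 survival
#' analysis (Cox + log-rank), per-visit genus differential abundance, PLS
#' metabolite discrimination at V3+V6, bile-acid ratios with within-arm
#' baseline-shift tests, and the KO-metabolite correlation matrix.
#'
#' @param cohort A `synthetic_cohort` (or an equivalently shaped list with
#'   `metadata`, `counts`, `metabolites`, `ko`).
#' @param out_dir Output directory for the results bundle (`NULL` = do not
#'   write files).
#' @param stratum Restrict the analysis to `"EE"`, `"LE"`, or `"all"`.
#' @param k_range,repeats DMM model-selection grid.
#' @param target_fct Target state for the survival analysis.
#' @param seed Master seed for all stochastic stages.
#' @return A list of class `fct_results` with every stage's outputs.
#' @export
run_full_analysis <- function(cohort, out_dir = NULL,
                              stratum = c("all", "EE", "LE"),
                              k_range = 2:10, repeats = 10L,
                              target_fct = 3L, seed = 1L) {
  stratum <- match.arg(stratum)
  meta <- validate_sample_table(cohort$metadata)
  if (stratum != "all") meta <- meta[meta$stratum == stratum, ]
  keep <- meta$sample_id
  counts <- cohort$counts[keep, , drop = FALSE]
  mtb <- cohort$metabolites[keep, , drop = FALSE]
  ko <- cohort$ko[keep, , drop = FALSE]

  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  log_stage("diversity", "rarefied Faith's PD on %d samples", nrow(counts))
  # a random coalescent tree stands in when no real phylogeny is given
  tree <- with_seed(child_seed(seed, "tree"),
                    ape::rcoal(ncol(counts), tip.label = colnames(counts)))
  pd_tab <- faith_pd_samples(counts, tree, rarefy_depth = min(rowSums(counts)),
                             seed = child_seed(seed, "rarefy"))

  log_stage("typecluster", "DMM selection over K = %s, %d repeats",
            paste(range(k_range), collapse = ".."), repeats)
  model <- select_dmm(counts, K_range = k_range, repeats = repeats,
                      seed = child_seed(seed, "dmm"))
  assignment <- order_fcts(fct_assign(model), meta)

  log_stage("trajectory", "transition graph and survival to FCT%d", target_fct)
  graph <- build_transition_graph(assignment, meta)
  surv <- fct_event_table(assignment, meta, target_fct)
  cox <- if (length(unique(surv$arm)) == 2L && sum(surv$event) > 0) {
    cox_binary(surv)
  } else NULL

  log_stage("diffabund", "per-visit genus comparisons")
  rel <- counts / rowSums(counts)
  diffabund <- lapply(stats::setNames(nm = c("V1", "V3", "V6")), function(v) {
    sel <- meta$visit == v
    if (length(unique(meta$arm[sel])) != 2L) return(NULL)
    compare_features(rel[sel, , drop = FALSE], meta$arm[sel], adjust = TRUE)
  })

  log_stage("metabolome", "PLS at V3+V6 and bile-acid ratios")
  sel <- meta$visit %in% c("V3", "V6")
  Y <- cbind(age = meta$age[sel],
             treatment = as.numeric(meta$arm[sel] == "test"))
  pls <- fit_pls(mtb[sel, , drop = FALSE], Y, n_components = 2L)
  vips <- vip(pls)
  pc <- p_corr(pls, component = 2L)
  wmw <- vapply(names(vips), function(m) {
    wmw_test(mtb[sel & meta$arm == "control", m],
             mtb[sel & meta$arm == "test", m])
  }, 1)
  decisions <- select_discriminant(vips, pc[names(vips)], wmw)
  ratios <- bile_acid_ratios(mtb[, intersect(bile_acid_panel(), colnames(mtb)),
                                 drop = FALSE])
  shift <- lapply(stats::setNames(nm = c("control", "test")), function(a) {
    baseline_shift_tests(stats::setNames(ratios$ba_cba, rownames(ratios)),
                         meta, a)
  })

  log_stage("integrate", "KO x metabolite Kendall matrix")
  sel_int <- meta$visit %in% c("V3", "V6")
  corr <- interdomain_matrix(ko[sel_int, , drop = FALSE],
                             mtb[sel_int, , drop = FALSE])
  leaf <- cluster_heatmap_order(corr)

  res <- structure(list(
    metadata = meta, faith_pd = pd_tab, dmm = model,
    evidence_table = attr(model, "evidence_table"),
    assignment = assignment, transition_graph = graph,
    survival = surv, cox = cox, diffabund = diffabund,
    pls = pls, decisions = decisions, bile_acid_ratios = ratios,
    baseline_shift = shift, interdomain = corr, heatmap_order = leaf,
    seed = seed), class = "fct_results")

  if (!is.null(out_dir)) write_results_bundle(res, out_dir)
  res
}

# Serialise the results bundle as TSV/JSON files plus a manifest.
write_results_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(res$faith_pd, "faith_pd.tsv")
  wt(res$evidence_table, "dmm_evidence.tsv")
  wt(res$assignment, "fct_assignment.tsv")
  wt(res$transition_graph$nodes, "transition_nodes.tsv")
  wt(res$transition_graph$edges, "transition_edges.tsv")
  wt(res$survival, "survival_records.tsv")
  wt(res$decisions, "metabolite_decisions.tsv")
  wt(cbind(sample_id = rownames(res$bile_acid_ratios),
           res$bile_acid_ratios), "bile_acid_ratios.tsv")
  for (v in names(res$diffabund)) {
    if (!is.null(res$diffabund[[v]])) {
      wt(res$diffabund[[v]], sprintf("diffabund_%s.tsv", v))
    }
  }
  write_matrix_tsv(res$interdomain$tau, file.path(out_dir, "interdomain_tau.tsv"),
                   id_column = "ko_id")
  write_matrix_tsv(res$interdomain$q, file.path(out_dir, "interdomain_q.tsv"),
                   id_column = "ko_id")
  if (!is.null(res$cox)) {
    jsonlite::write_json(unclass(res$cox), file.path(out_dir, "cox.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("fctomics")),
    seed = res$seed,
    n_samples = nrow(res$metadata),
    selected_K = res$dmm$K,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
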