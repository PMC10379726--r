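#' Read a taxa count table from TSV
#'
#' Reads a tab-separated count table with a header row and feature/sample
#' identifiers in the first column, validates that every cell is a
#' non-negative integer, and normalises the orientation to samples in rows.
#'
#' @param path Path to a TSV file.
#' @param orientation `"samples"` if samples are in rows (the default), or
#'   `"taxa"` if taxa are in rows and samples in columns.
#' @param level Taxonomic level tag attached to the matrix; one of
#'   `"genus"`, `"species"`, `"MGS"`.
#' @return An integer matrix (samples x taxa) with `level` attribute.
#' @export
read_count_table <- function(path, orientation = c("samples", "taxa"),
                             level = c("genus", "species", "MGS")) {
  orientation <- match.arg(orientation)
  level <- match.arg(level)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs an ID column plus data columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicated row IDs in count table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(colnames(df)[-1L])) {
    stop("duplicated column IDs in count table")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-integer or negative count at row '%s', column '%s'",
                 ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  rownames(m) <- ids
  if (orientation == "taxa") m <- t(m)
  storage.mode(m) <- "integer"
  attr(m, "level") <- level
  m
}

#' Write a numeric matrix as TSV (samples in rows)
#'
#' @param m Matrix with row and column names.
#' @param path Output path.
#' @param id_column Name used for the leading identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_column = "sample_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a numeric (metabolite or KO) matrix from TSV
#'
#' Like [read_count_table()] but for non-negative real-valued tables;
#' missing values (`NA`) are retained.
#'
#' @inheritParams read_count_table
#' @return A numeric matrix, samples x features.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicated sample IDs in feature table")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop("negative value in feature table")
  rownames(m) <- ids
  m
}

#' Read a sample metadata table
#'
#' Expects columns `sample_id`, `infant_id`, `visit`, `age`, `arm`, and
#' optionally `stratum` (recomputed from the baseline age when absent).
#'
#' @param path Path to a TSV file.
#' @return A validated `data.frame` of sample metadata.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_table(df)
}

#' @rdname read_sample_table
#' @param metadata A candidate sample metadata `data.frame`.
#' @export
validate_sample_table <- function(metadata) {
  need <- c("sample_id", "infant_id", "visit", "age", "arm")
  miss <- setdiff(need, colnames(metadata))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id)) stop("duplicated sample_id in metadata")
  if (any(metadata$age < 0)) stop("negative age in metadata")
  bad_visit <- setdiff(unique(metadata$visit), c("V0", "V1", "V3", "V6"))
  if (length(bad_visit)) stop("unknown visit labels: ", paste(bad_visit, collapse = ", "))
  bad_arm <- setdiff(unique(metadata$arm), c("control", "test"))
  if (length(bad_arm)) stop("unknown arm labels: ", paste(bad_arm, collapse = ", "))
  if (anyDuplicated(metadata[, c("infant_id", "visit")])) {
    stop("an (infant_id, visit) pair appears more than once")
  }
  if (!"stratum" %in% colnames(metadata)) {
    base_age <- stats::aggregate(age ~ infant_id, metadata, min)
    metadata$stratum <- assign_cohort(
      base_age$age[match(metadata$infant_id, base_age$infant_id)])
  }
  metadata
}

#' Read a phylogenetic tree in newick format
#'
#' Thin wrapper around [ape::read.tree()] validating that the result is a
#' single tree with uniquely labelled leaves; missing branch lengths are
#' treated as zero.
#'
#' @param path Path to a newick file (single tree).
#' @return An object of class `phylo`.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) stop("malformed newick: ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed newick: could not parse tree")
  if (inherits(tree, "multiPhylo")) stop("expected a single tree, got several")
  if (anyDuplicated(tree$tip.label)) stop("duplicated leaf labels in tree")
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  tree
}

#' Rarefy a count vector or matrix to fixed depth
#'
#' Subsamples reads without replacement (multivariate hypergeometric),
#' matching the behaviour of [vegan::rrarefy()]. Samples whose library size
#' is below `depth` are dropped with a warning rather than silently kept.
#'
#' @param counts A non-negative integer vector, or a samples x taxa matrix.
#' @param depth Target depth. For matrices the default is the minimum
#'   library size across samples.
#' @param seed Integer seed for the subsampling.
#' @return Rarefied counts with the same shape (minus dropped samples).
#' @export
rarefy <- function(counts, depth = NULL, seed = 1L) {
  if (is.matrix(counts)) return(rarefy_counts(counts, depth, seed))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  total <- sum(counts)
  if (is.null(depth)) depth <- total
  if (depth > total) stop("rarefaction depth exceeds library size")
  if (depth == total) return(counts)
  with_seed(seed, {
    # vegan warns heuristically when the smallest count exceeds 1; counts
    # are already validated as integers above
    out <- drop(suppressWarnings(vegan::rrarefy(matrix(counts, nrow = 1L),
                                                depth)))
  })
  names(out) <- names(counts)
  out
}

#' @rdname rarefy
#' @export
rarefy_counts <- function(counts, depth = NULL, seed = 1L) {
  totals <- rowSums(counts)
  if (is.null(depth)) depth <- min(totals)
  keep <- totals >= depth
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) below rarefaction depth ", depth,
            " dropped: ", paste(rownames(counts)[!keep], collapse = ", "))
  }
  kept <- counts[keep, , drop = FALSE]
  with_seed(seed, {
    out <- suppressWarnings(vegan::rrarefy(kept, depth))
  })
  storage.mode(out) <- "integer"
  out
}

#' Assign the enrollment stratum from baseline age
#'
#' Infants aged at most 90 days at the baseline visit form the early
#' enrollment (EE) stratum; older infants the late enrollment (LE) stratum.
#'
#' @param baseline_age Age in days at the baseline visit (vectorised).
#' @param cutoff Stratum cutoff in days (default 90).
#' @return Character vector of `"EE"`/`"LE"`.
#' @export
assign_cohort <- function(baseline_age, cutoff = 90) {
  if (any(is.na(baseline_age)) || any(baseline_age < 0)) {
    stop("baseline age must be non-negative")
  }
  ifelse(baseline_age <= cutoff, "EE", "LE")
}

# Align several samples x features tables on a common sample set, failing
# loudly when IDs mismatch.
align_samples <- function(..., require_all = TRUE) {
  tabs <- list(...)
  ids <- Reduce(intersect, lapply(tabs, rownames))
  if (length(ids) == 0L) stop("no overlapping sample IDs across tables")
  if (require_all) {
    sizes <- vapply(tabs, nrow, 1L)
    if (any(sizes != length(ids))) {
      stop("sample IDs differ across tables (",
           paste(sizes, collapse = "/"), " rows vs ", length(ids), " shared)")
    }
  }
  lapply(tabs, function(t) t[ids, , drop = FALSE])
}
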