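# Ecological measures: Faith's phylogenetic diversity (alpha) and
# Bray-Curtis dissimilarity (beta).

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal rooted subtree spanning the observed
#' taxa, including the path to the root (the rooted-tree PD definition).
#' Computed via [picante::pd()]. Taxa absent from the tree are dropped with
#' a warning; an empty taxon set yields 0 with a warning.
#'
#' @param presence Character vector of present taxa, or a logical/numeric
#'   vector named by taxon (values > 0 mark presence).
#' @param tree A rooted `phylo` tree whose tip labels cover the taxa.
#' @return Non-negative PD value.
#' @export
faith_pd <- function(presence, tree) {
  if (!is.character(presence)) {
    if (is.null(names(presence))) stop("non-character `presence` must be named")
    presence <- names(presence)[presence > 0]
  }
  missing <- setdiff(presence, tree$tip.label)
  if (length(missing)) {
    warning("taxa absent from tree dropped: ", paste(missing, collapse = ", "))
    presence <- setdiff(presence, missing)
  }
  if (length(presence) == 0L) {
    warning("empty taxon set; PD = 0")
    return(0)
  }
  comm <- matrix(0, nrow = 1L, ncol = length(tree$tip.label),
                 dimnames = list("s", tree$tip.label))
  comm[1L, presence] <- 1
  as.numeric(picante::pd(comm, tree, include.root = TRUE)$PD)
}

#' Per-sample Faith's PD from a count matrix
#'
#' Presence is taken as count > 0, optionally after rarefaction.
#'
#' @param counts Samples x taxa count matrix.
#' @param tree Rooted `phylo` tree.
#' @param rarefy_depth Optional depth; when given, counts are rarefied
#'   first (samples below the depth are dropped, see [rarefy_counts()]).
#' @param seed Seed for the rarefaction.
#' @return `data.frame` with `sample_id` and `faith_pd`.
#' @export
faith_pd_samples <- function(counts, tree, rarefy_depth = NULL, seed = 1L) {
  if (!is.null(rarefy_depth)) {
    counts <- rarefy_counts(counts, rarefy_depth, seed)
  }
  shared <- intersect(colnames(counts), tree$tip.label)
  if (length(shared) < ncol(counts)) {
    warning(ncol(counts) - length(shared), " taxa absent from tree dropped")
  }
  comm <- (counts[, shared, drop = FALSE] > 0) * 1
  res <- picante::pd(comm, tree, include.root = TRUE)
  data.frame(sample_id = rownames(counts), faith_pd = res$PD,
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity
#'
#' `1 - 2 * sum(min(a, b)) / (sum(a) + sum(b))`, computed with
#' [vegan::vegdist()]; bounded in `[0, 1]` for non-negative abundances.
#'
#' @param a,b Non-negative abundance vectors of equal length.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (any(a < 0) || any(b < 0)) stop("abundances must be non-negative")
  if (sum(a) == 0 && sum(b) == 0) stop("Bray-Curtis undefined for two empty samples")
  as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
}

#' Pairwise Bray-Curtis distance matrix
#'
#' @param counts Samples x taxa abundance matrix.
#' @return A `dist` object over samples.
#' @export
bray_curtis_matrix <- function(counts) {
  if (any(rowSums(counts) == 0)) stop("all-zero sample in abundance matrix")
  vegan::vegdist(counts, method = "bray")
}
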