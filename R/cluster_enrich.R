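#' Min-Max scaling of similarity scores
#'
#' Linearly rescales scores to `[0, 1]` using the minimum and maximum over
#' the analyzed protein set (not global constants). Rank order is
#' preserved; a constant vector maps to all 0.5 with a warning.
#'
#' @param scores Numeric vector or matrix.
#' @return Rescaled object of the same shape.
#' @export
minmax_scale <- function(scores) {
  lo <- min(scores); hi <- max(scores)
  if (hi == lo) {
    warning("constant scores; Min-Max scaling undefined, returning 0.5")
    scores[] <- 0.5
    return(scores)
  }
  (scores - lo) / (hi - lo)
}

#' Distance matrix from Min-Max-scaled similarities
#'
#' `d = 1 - scaled similarity`, with the diagonal forced to zero and the
#' matrix symmetrized. Note that `1 - MM` is not guaranteed to satisfy the
#' triangle inequality for arbitrary similarity matrices; it is used here
#' as a dissimilarity for agglomerative clustering, which does not require
#' it.
#'
#' @param scaled Symmetric numeric matrix of similarities in `[0, 1]`
#'   (e.g. a Min-Max-scaled [protein_similarity_matrix()]).
#' @return Symmetric distance matrix in `[0, 1]`, zero diagonal, same
#'   dimnames.
#' @export
to_distance <- function(scaled) {
  stopifnot(is.matrix(scaled), nrow(scaled) == ncol(scaled))
  if (any(scaled < 0 | scaled > 1)) {
    stop("similarities must lie in [0, 1]; apply minmax_scale() first")
  }
  d <- 1 - (scaled + t(scaled)) / 2
  diag(d) <- 0
  d
}

#' Complete-linkage clustering of a distance matrix
#'
#' Agglomerative clustering where the distance between clusters is the
#' maximum pairwise distance, cut into `k` groups.
#'
#' @param d Symmetric distance matrix (or `dist` object).
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer vector of cluster labels named by the genes, with the
#'   `hclust` tree attached as attribute `"tree"`.
#' @export
complete_linkage <- function(d, k) {
  dd <- if (inherits(d, "dist")) d else stats::as.dist(d)
  n <- attr(dd, "Size")
  stopifnot(k >= 1L, k <= n)
  tree <- stats::hclust(dd, method = "complete")
  labels <- stats::cutree(tree, k = k)
  attr(labels, "tree") <- tree
  labels
}

#' Hypergeometric enrichment of a category in a cluster
#'
#' Upper-tail probability of observing at least the actual overlap between
#' a cluster and a gene category when drawing the cluster uniformly from
#' the universe.
#'
#' @param cluster Character vector of genes in the cluster.
#' @param category Character vector of genes carrying the category label.
#' @param universe Character vector of all genes under analysis.
#' @return The p-value `P(X >= overlap)`.
#' @export
hypergeom_enrich <- function(cluster, category, universe) {
  cluster <- intersect(unique(cluster), universe)
  category <- intersect(unique(category), universe)
  x <- length(intersect(cluster, category))
  stats::phyper(x - 1, length(category),
                length(universe) - length(category), length(cluster),
                lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up BH adjustment with a significance call at the given
#' FDR level.
#'
#' @param pvals Numeric vector of p-values.
#' @param alpha FDR level, default 0.01.
#' @return List with `fdr` (adjusted values) and `significant`
#'   (`fdr <= alpha`).
#' @export
bh_fdr <- function(pvals, alpha = 0.01) {
  fdr <- stats::p.adjust(pvals, method = "BH")
  list(fdr = fdr, significant = fdr <= alpha)
}

#' Enrichment table for a clustering
#'
#' Tests every cluster against every category with the hypergeometric
#' upper tail and adjusts all tests jointly by Benjamini-Hochberg. The
#' universe is the full set of clustered genes.
#'
#' @param labels Named integer vector of cluster labels (as from
#'   [complete_linkage()]).
#' @param categories Named character vector: gene -> category label.
#' @param alpha FDR level, default 0.01.
#' @return data.frame with `cluster`, `category`, `cluster_size`,
#'   `category_size`, `overlap`, `p`, `fdr`, `significant`.
#' @export
cluster_enrichment <- function(labels, categories, alpha = 0.01) {
  universe <- names(labels)
  stopifnot(!is.null(universe), !is.null(names(categories)))
  grid <- expand.grid(cluster = sort(unique(labels)),
                      category = sort(unique(categories)),
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(r) {
    cl_genes <- universe[labels == grid$cluster[r]]
    cat_genes <- intersect(names(categories)[categories == grid$category[r]],
                           universe)
    data.frame(cluster = grid$cluster[r], category = grid$category[r],
               cluster_size = length(cl_genes),
               category_size = length(cat_genes),
               overlap = length(intersect(cl_genes, cat_genes)),
               p = hypergeom_enrich(cl_genes, cat_genes, universe),
               row.names = NULL)
  }))
  adj <- bh_fdr(res$p, alpha = alpha)
  res$fdr <- adj$fdr
  res$significant <- adj$significant
  res
}

#' Co-clustering accuracy against known categories
#'
#' Fraction of genes assigned to the majority cluster of their category,
#' maximized over the assignment of clusters to categories (greedy on the
#' contingency table; exact for two categories). Used to compare raw
#' versus normalized distances on corpora with planted categories.
#'
#' @param labels Named cluster labels.
#' @param categories Named gene -> category vector.
#' @return Accuracy in `[0, 1]`.
#' @export
coclustering_accuracy <- function(labels, categories) {
  categories <- categories[names(labels)]
  tab <- table(categories, labels)
  total <- 0
  # greedy maximum matching of categories to clusters
  while (nrow(tab) > 0 && ncol(tab) > 0) {
    best <- which(tab == max(tab), arr.ind = TRUE)[1L, ]
    total <- total + tab[best[1L], best[2L]]
    tab <- tab[-best[1L], -best[2L], drop = FALSE]
  }
  as.numeric(total / length(labels))
}
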