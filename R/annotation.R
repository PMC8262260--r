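#' Log-normalise a count matrix
#'
#' Counts-per-10k followed by log1p; the standard normalisation feeding
#' clustering, marker selection and module scores.
#'
#' @param counts genes x barcodes matrix (sparse or dense).
#' @param scale_factor library-size target (default 1e4).
#' @return A dense matrix of log-normalised expression.
#' @keywords internal
normalize_log <- function(counts, scale_factor = 1e4) {
  depth <- Matrix::colSums(counts)
  depth[depth == 0] <- 1
  m <- as.matrix(counts %*% Matrix::Diagonal(x = scale_factor / depth))
  dimnames(m) <- dimnames(counts)
  log1p(m)
}

#' Cluster droplets on principal components
#'
#' Plumbing clusterer standing in for externally supplied labels: principal
#' components of the log-normalised matrix, a k-nearest-neighbour graph, and
#' Louvain community detection. Deterministic given \code{seed}.
#'
#' @param expr an \code{\link{expression_matrix}} (QC-filtered).
#' @param n_pcs number of principal components (reduced with a warning when
#'   the data have fewer usable dimensions).
#' @param resolution Louvain resolution.
#' @param k neighbours per droplet in the kNN graph.
#' @param seed integer seed.
#' @return Named character vector: barcode to cluster id.
#' @export
assign_clusters <- function(expr, n_pcs = 30, resolution = 1.0, k = 15,
                            seed = 1) {
  norm <- normalize_log(expr$counts)
  x <- t(norm)
  max_pcs <- min(nrow(x) - 1L, ncol(x))
  if (n_pcs > max_pcs) {
    warning("reducing n_pcs to ", max_pcs)
    n_pcs <- max_pcs
  }
  pcs <- stats::prcomp(x, center = TRUE, scale. = FALSE,
                       rank. = n_pcs)$x
  g <- knn_graph(pcs, k = min(k, nrow(pcs) - 1L))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  stats::setNames(as.character(igraph::membership(comm)), rownames(pcs))
}

# undirected kNN graph from a coordinate matrix (euclidean)
knn_graph <- function(coords, k) {
  n <- nrow(coords)
  sq <- rowSums(coords^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(coords)
  diag(d2) <- Inf
  edges <- vapply(seq_len(n),
                  function(i) order(d2[i, ])[seq_len(k)],
                  integer(k))
  el <- cbind(rep(seq_len(n), each = k), as.vector(edges))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- rownames(coords)
  g
}

#' Name clusters by canonical marker expression
#'
#' Assigns each cluster the cell-type whose marker set has the highest mean
#' log-normalised expression within the cluster. This is how a user turns
#' anonymous cluster ids into the broad cell-type vocabulary the doublet
#' rules and the antibody map speak.
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param clusters named vector (barcode to cluster id).
#' @param marker_sets named list: cell type to character vector of marker
#'   genes.
#' @return Named character vector mapping each barcode to a cell-type name.
#'   The cluster-to-type map is attached as attribute \code{"cluster_map"}.
#' @export
annotate_clusters <- function(expr, clusters, marker_sets) {
  norm <- normalize_log(expr$counts)
  cl_ids <- unique(clusters)
  score <- sapply(marker_sets, function(genes) {
    genes <- intersect(genes, rownames(norm))
    if (!length(genes)) return(rep(NA_real_, length(cl_ids)))
    m <- colMeans(norm[genes, names(clusters), drop = FALSE])
    vapply(cl_ids, function(cl) mean(m[clusters == cl]), numeric(1))
  })
  score <- matrix(score, nrow = length(cl_ids),
                  dimnames = list(cl_ids, names(marker_sets)))
  cluster_map <- stats::setNames(colnames(score)[max.col(score)], cl_ids)
  out <- stats::setNames(cluster_map[clusters], names(clusters))
  attr(out, "cluster_map") <- cluster_map
  out
}

#' Per-cluster marker genes (one-vs-rest rank-sum)
#'
#' For each cluster, a Wilcoxon rank-sum test of each gene against all other
#' droplets (normal approximation with tie correction), Benjamini-Hochberg
#' adjusted; genes with adjusted p < \code{alpha} are ranked by log2
#' fold-change and the top \code{top_n} returned.
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param labels named vector (barcode to cluster/cell type).
#' @param top_n markers per cluster.
#' @param alpha BH-adjusted significance cutoff.
#' @param min_cells clusters smaller than this are skipped with a warning.
#' @return Named list: cluster to character vector of marker genes (possibly
#'   shorter than \code{top_n} when fewer genes are significant).
#' @export
marker_genes <- function(expr, labels, top_n = 5, alpha = 0.05,
                         min_cells = 3) {
  labels <- labels[intersect(names(labels), colnames(expr$counts))]
  if (length(unique(labels)) < 2)
    stop("marker selection needs at least two clusters")
  norm <- normalize_log(expr$counts[, names(labels), drop = FALSE])
  out <- list()
  for (cl in sort(unique(labels))) {
    in_cl <- labels == cl
    if (sum(in_cl) < min_cells) {
      warning("cluster ", cl, " has fewer than ", min_cells,
              " cells; skipped")
      out[[cl]] <- character(0)
      next
    }
    p <- rank_sum_pvalues(norm, in_cl)
    padj <- stats::p.adjust(p, method = "BH")
    lfc <- log2((rowMeans(norm[, in_cl, drop = FALSE]) + 1e-9) /
                (rowMeans(norm[, !in_cl, drop = FALSE]) + 1e-9))
    sig <- which(padj < alpha & lfc > 0)
    sig <- sig[order(lfc[sig], decreasing = TRUE)]
    out[[cl]] <- rownames(norm)[utils::head(sig, top_n)]
  }
  out
}

# vectorised two-sided Wilcoxon rank-sum p-values, gene-wise, group vs rest
rank_sum_pvalues <- function(mat, in_group) {
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  n <- n1 + n2
  ranks <- t(apply(mat, 1, rank))
  w <- rowSums(ranks[, in_group, drop = FALSE]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  # tie correction per gene
  tie_term <- apply(mat, 1, function(x) {
    t <- table(x)
    sum(t^3 - t)
  })
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  sigma2[sigma2 <= 0] <- NA
  z <- (w - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  p[is.na(p)] <- 1
  p
}

#' Cell-type module scores
#'
#' For each gene set, the mean log-normalised expression of the set minus the
#' mean of expression-matched control genes: all genes are binned into
#' \code{n_bins} equal-frequency bins by average expression, and for each set
#' gene \code{n_ctrl} control genes are drawn (seeded) from its bin; the
#' control pool is the union of those draws. High scores mark droplets whose
#' transcriptome resembles the set's cell type; a hybrid doublet transcriptome
#' scores high on two types at once, which is what the classifier exploits.
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param gene_sets named list of character vectors; genes absent from the
#'   matrix are dropped with a warning.
#' @param n_bins expression bins for control matching.
#' @param n_ctrl control genes sampled per set gene.
#' @param seed integer seed for control sampling.
#' @return Matrix, barcodes x gene sets.
#' @export
module_scores <- function(expr, gene_sets, n_bins = 24, n_ctrl = 100,
                          seed = 1) {
  norm <- normalize_log(expr$counts)
  avg <- rowMeans(norm)
  n_bins <- min(n_bins, length(avg))
  bin <- ceiling(rank(avg, ties.method = "first") * n_bins / length(avg))
  by_bin <- split(names(avg), bin)
  scores <- matrix(NA_real_, ncol(norm), length(gene_sets),
                   dimnames = list(colnames(norm), names(gene_sets)))
  set.seed(seed)
  for (j in seq_along(gene_sets)) {
    genes <- gene_sets[[j]]
    present <- intersect(genes, rownames(norm))
    if (length(present) < length(genes))
      warning("dropping ", length(genes) - length(present),
              " gene(s) absent from the matrix in set ",
              names(gene_sets)[j])
    if (!length(present)) {
      warning("gene set ", names(gene_sets)[j],
              " is empty after filtering; scores are NaN")
      scores[, j] <- NaN
      next
    }
    ctrl <- unique(unlist(lapply(present, function(g) {
      pool <- by_bin[[as.character(bin[g])]]
      sample(pool, min(n_ctrl, length(pool)))
    })))
    scores[, j] <- colMeans(norm[present, , drop = FALSE]) -
      colMeans(norm[ctrl, , drop = FALSE])
  }
  scores
}
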