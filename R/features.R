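#' Quality-control filter for droplets
#'
#' Retains droplets with more than \code{min_genes} detected genes, more than
#' \code{min_umi} UMIs and less than \code{max_pct_mito} percent mitochondrial
#' UMIs. All three comparisons are strict, so a droplet sitting exactly on a
#' threshold is excluded.
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param min_genes minimum detected genes (exclusive).
#' @param min_umi minimum UMI count (exclusive).
#' @param max_pct_mito maximum mitochondrial UMI percentage (exclusive).
#' @param mito_pattern regex identifying mitochondrial genes ("^MT-" for
#'   human, "^mt-" for mouse).
#' @return Character vector of retained barcodes.
#' @export
qc_filter <- function(expr, min_genes = 500, min_umi = 1000,
                      max_pct_mito = 25, mito_pattern = "^MT-") {
  counts <- expr$counts
  n_genes <- Matrix::colSums(counts > 0)
  n_umi <- Matrix::colSums(counts)
  mito <- grepl(mito_pattern, rownames(counts))
  pct_mito <- ifelse(n_umi > 0,
                     100 * Matrix::colSums(counts[mito, , drop = FALSE]) / n_umi,
                     0)
  keep <- n_genes > min_genes & n_umi > min_umi & pct_mito < max_pct_mito
  if (!any(keep)) stop("no droplets pass the QC filter")
  colnames(counts)[keep]
}

#' Mito-ribo ratio
#'
#' The apoptosis covariate m / (m + r), where m is the per-droplet
#' mitochondrial UMI percentage and r the ribosomal-protein UMI percentage.
#' Rises toward 1 in apoptotic and low-quality droplets (mitochondrial
#' transcripts retained, ribosomal-protein transcripts depleted). Defined as
#' 0 when both percentages are 0, since such droplets carry no apoptosis
#' signal.
#'
#' @param pct_mito,pct_ribo percentages in [0, 100], vectorised.
#' @return Numeric vector in [0, 1].
#' @export
mito_ribo_ratio <- function(pct_mito, pct_ribo) {
  if (any(pct_mito < 0) || any(pct_ribo < 0))
    stop("percentages must be non-negative")
  denom <- pct_mito + pct_ribo
  ifelse(denom > 0, pct_mito / denom, 0)
}

#' Centred log-ratio transform
#'
#' y_i = ln(x_i + pseudocount) - mean_j ln(x_j + pseudocount). The transformed
#' values sum to zero exactly.
#'
#' @param x non-negative numeric vector, length >= 2.
#' @param pseudocount added inside the log to admit zero counts.
#' @return Numeric vector of the same length, summing to 0.
#' @export
clr_vector <- function(x, pseudocount = 1) {
  if (length(x) < 2) stop("CLR needs at least two values")
  if (any(x < 0)) stop("CLR input must be non-negative")
  lx <- log(x + pseudocount)
  lx - mean(lx)
}

#' CLR-normalise an ADT matrix
#'
#' Applies \code{\link{clr_vector}} per droplet across the antibody panel,
#' independently within each sample, and fills the \code{clr} slot.
#'
#' @param adt an \code{\link{adt_matrix}}.
#' @param pseudocount see \code{\link{clr_vector}}.
#' @return The \code{adt_matrix} with \code{clr} filled.
#' @export
clr_adt <- function(adt, pseudocount = 1) {
  counts <- as.matrix(adt$counts)
  if (nrow(counts) < 2)
    warning("single-antibody panel: CLR is identically zero")
  lx <- log(counts + pseudocount)
  clr <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  # sample-wise for interface symmetry; the per-droplet margin makes the
  # transform independent across droplets anyway
  for (s in unique(adt$sample_id)) {
    idx <- which(adt$sample_id == s)
    block <- lx[, idx, drop = FALSE]
    if (nrow(counts) >= 2)
      clr[, idx] <- sweep(block, 2, colMeans(block))
  }
  adt$clr <- clr
  adt
}

# per-sample CLR of a scalar per-droplet covariate
clr_by_sample <- function(x, sample_id, pseudocount = 1) {
  out <- numeric(length(x))
  for (s in unique(sample_id)) {
    idx <- which(sample_id == s)
    out[idx] <- if (length(idx) >= 2) clr_vector(x[idx], pseudocount)
    else 0
  }
  out
}

#' Assemble the per-droplet feature table
#'
#' Computes the droplet covariates the doublet classifier consumes: detected
#' genes, UMI count, mitochondrial and ribosomal-protein UMI percentages, the
#' mito-ribo ratio, total VDJ UMIs on the supplied (already filtered) contigs,
#' and the per-sample CLR transforms of the count covariates. Droplets with no
#' VDJ capture contribute a count of 0 to the CLR (via the pseudocount), not a
#' missing value.
#'
#' @param expr an \code{\link{expression_matrix}} (QC-filtered).
#' @param contigs optional contig table (pass the output of
#'   \code{\link{filter_contigs}}); when absent, VDJ UMI counts are 0.
#' @param mito_pattern,ribo_pattern regexes for mitochondrial and
#'   ribosomal-protein genes (human defaults "^MT-" and "^RP[SL]").
#' @param pseudocount pseudocount used in every CLR.
#' @return \code{data.frame} with one row per droplet: barcode, sample_id,
#'   n_genes, n_umi, pct_mito, pct_ribo, mito_ribo_ratio, n_umi_vdj,
#'   clr_n_umi, clr_n_genes, clr_n_umi_vdj.
#' @export
droplet_features <- function(expr, contigs = NULL, mito_pattern = "^MT-",
                             ribo_pattern = "^RP[SL]", pseudocount = 1) {
  counts <- expr$counts
  barcodes <- colnames(counts)
  n_genes <- Matrix::colSums(counts > 0)
  n_umi <- Matrix::colSums(counts)
  mito <- grepl(mito_pattern, rownames(counts))
  ribo <- grepl(ribo_pattern, rownames(counts))
  pct_mito <- ifelse(n_umi > 0,
                     100 * Matrix::colSums(counts[mito, , drop = FALSE]) / n_umi, 0)
  pct_ribo <- ifelse(n_umi > 0,
                     100 * Matrix::colSums(counts[ribo, , drop = FALSE]) / n_umi, 0)
  n_umi_vdj <- stats::setNames(rep(0, length(barcodes)), barcodes)
  if (!is.null(contigs) && nrow(contigs)) {
    sums <- tapply(contigs$umis, contigs$barcode, sum)
    hit <- intersect(names(sums), barcodes)
    n_umi_vdj[hit] <- sums[hit]
  }
  sid <- expr$sample_id
  data.frame(
    barcode = barcodes,
    sample_id = unname(sid),
    n_genes = unname(n_genes),
    n_umi = unname(n_umi),
    pct_mito = unname(pct_mito),
    pct_ribo = unname(pct_ribo),
    mito_ribo_ratio = mito_ribo_ratio(unname(pct_mito), unname(pct_ribo)),
    n_umi_vdj = unname(n_umi_vdj),
    clr_n_umi = clr_by_sample(unname(n_umi), sid, pseudocount),
    clr_n_genes = clr_by_sample(unname(n_genes), sid, pseudocount),
    clr_n_umi_vdj = clr_by_sample(unname(n_umi_vdj), sid, pseudocount),
    stringsAsFactors = FALSE)
}
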