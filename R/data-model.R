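#' Construct a gene-expression count matrix
#'
#' Container for raw UMI counts from droplet-based scRNA-seq: a sparse
#' genes-by-barcodes integer matrix together with a per-barcode sample
#' identifier. All downstream QC, feature extraction and simulation functions
#' operate on this class.
#'
#' @param counts genes x barcodes matrix (dense or \code{Matrix} sparse) of
#'   non-negative integer UMI counts, with gene symbols as rownames and
#'   droplet barcodes as colnames.
#' @param sample_id character scalar or per-barcode character vector naming
#'   the sample each droplet came from.
#' @return An object of class \code{expression_matrix}: a list with elements
#'   \code{counts} (a \code{dgCMatrix}) and \code{sample_id} (named character
#'   vector, one entry per barcode).
#' @export
expression_matrix <- function(counts, sample_id = "sample1") {
  counts <- as_count_matrix(counts, what = "expression")
  if (nrow(counts) == 0L) stop("gene list must be non-empty")
  sample_id <- expand_sample_id(sample_id, colnames(counts))
  structure(list(counts = counts, sample_id = sample_id),
            class = "expression_matrix")
}

#' Construct an antibody-capture (ADT) count matrix
#'
#' Container for CITE-seq antibody-derived tag counts: antibodies by barcodes.
#' The \code{clr} slot holds the centred log-ratio transform once
#' \code{\link{clr_adt}} has been applied.
#'
#' @param counts antibodies x barcodes matrix of non-negative integer counts.
#' @param sample_id character scalar or per-barcode vector of sample names.
#' @param clr optional matrix of the same shape holding CLR-normalised values.
#' @return An object of class \code{adt_matrix}.
#' @export
adt_matrix <- function(counts, sample_id = "sample1", clr = NULL) {
  counts <- as_count_matrix(counts, what = "ADT")
  if (nrow(counts) == 0L) stop("antibody panel must be non-empty")
  sample_id <- expand_sample_id(sample_id, colnames(counts))
  if (!is.null(clr)) {
    clr <- as.matrix(clr)
    if (!identical(dim(clr), dim(counts)))
      stop("clr matrix must match the shape of counts")
    dimnames(clr) <- dimnames(counts)
  }
  structure(list(counts = counts, sample_id = sample_id, clr = clr),
            class = "adt_matrix")
}

# shared validation: coerce to sparse, check integrality / names
as_count_matrix <- function(counts, what) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop(what, " counts must be non-negative integers")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop(what, " counts need row (feature) and column (barcode) names")
  if (anyDuplicated(colnames(counts)))
    stop("barcodes must be unique")
  counts
}

expand_sample_id <- function(sample_id, barcodes) {
  if (length(sample_id) == 1L) sample_id <- rep(sample_id, length(barcodes))
  if (length(sample_id) != length(barcodes))
    stop("sample_id must be scalar or one value per barcode")
  stats::setNames(as.character(sample_id), barcodes)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d droplets, %d sample(s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$sample_id))))
  invisible(x)
}

#' @export
print.adt_matrix <- function(x, ...) {
  cat(sprintf("adt_matrix: %d antibodies x %d droplets, CLR %s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$clr)) "not computed" else "computed"))
  invisible(x)
}

#' Subset droplets of an expression or ADT matrix
#'
#' @param x an \code{expression_matrix} or \code{adt_matrix}.
#' @param barcodes character vector of barcodes to keep (order preserved).
#' @return An object of the same class restricted to \code{barcodes}.
#' @export
subset_barcodes <- function(x, barcodes) {
  stopifnot(all(barcodes %in% colnames(x$counts)))
  x$counts <- x$counts[, barcodes, drop = FALSE]
  x$sample_id <- x$sample_id[barcodes]
  if (!is.null(x$clr)) x$clr <- x$clr[, barcodes, drop = FALSE]
  x
}
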