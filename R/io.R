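#' Read a gene-expression count matrix
#'
#' Reads 10x-style Matrix Market triplet directories (\code{matrix.mtx} plus
#' \code{features.tsv}/\code{genes.tsv} and \code{barcodes.tsv}) or a dense
#' CSV (genes in rows, barcodes in columns). When \code{sample_id} is given,
#' barcodes are suffixed with it (\code{<barcode>_<sample_id>}) so that
#' barcodes remain globally unique when several samples are merged.
#'
#' 10x HDF5 input is not supported by this build; convert to the Matrix
#' Market triplet layout first.
#'
#' @param path directory (MTX triplet) or file (CSV).
#' @param format one of \code{"auto"}, \code{"mtx"}, \code{"csv"}.
#' @param sample_id optional sample name; when supplied, barcodes are suffixed
#'   with it and the sample recorded per droplet. Defaults to no suffix and
#'   sample \code{"sample1"}.
#' @return An \code{\link{expression_matrix}}.
#' @export
read_expression <- function(path, format = c("auto", "mtx", "csv", "h5"),
                            sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input path does not exist: ", path)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx"
    else if (grepl("\\.(h5|hdf5)$", path)) "h5"
    else "csv"
  }
  if (format == "h5")
    stop("10x HDF5 input is not supported; export the MTX triplet instead")
  counts <- if (format == "mtx") read_mtx_dir(path) else read_dense_csv(path)
  if (length(counts) == 0L || ncol(counts) == 0L)
    stop("no droplets found in ", path)
  sid <- if (is.null(sample_id)) "sample1" else sample_id
  if (!is.null(sample_id))
    colnames(counts) <- paste(colnames(counts), sample_id, sep = "_")
  expression_matrix(counts, sample_id = sid)
}

read_mtx_dir <- function(path) {
  mtx <- first_existing(path, c("matrix.mtx", "matrix.mtx.gz"))
  feat <- first_existing(path, c("features.tsv", "genes.tsv",
                                 "features.tsv.gz", "genes.tsv.gz"))
  bcs <- first_existing(path, c("barcodes.tsv", "barcodes.tsv.gz"))
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("malformed MTX file: ",
                                         conditionMessage(e)))
  features <- utils::read.delim(feat, header = FALSE,
                                stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(bcs, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(features) != nrow(m) || length(barcodes) != ncol(m))
    stop("feature/barcode table lengths do not match the matrix dimensions")
  # 10x features.tsv carries <id> <symbol> [<type>]; prefer the symbol column
  rownames(m) <- make.unique(if (ncol(features) >= 2) features[[2]]
                             else features[[1]])
  colnames(m) <- barcodes
  m
}

first_existing <- function(dir, names) {
  for (nm in names) {
    p <- file.path(dir, nm)
    if (file.exists(p)) return(p)
  }
  stop("missing ", names[1], " in ", dir)
}

read_dense_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty count table: ", path)
  as.matrix(df)
}

#' Write an expression matrix as a Matrix Market triplet directory
#'
#' Inverse of \code{\link{read_expression}} on the MTX format; the round trip
#' is lossless on integer counts.
#'
#' @param x an \code{expression_matrix} (or \code{adt_matrix}).
#' @param dir output directory, created if needed.
#' @return \code{dir}, invisibly.
#' @export
write_expression <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(id = rownames(x$counts), name = rownames(x$counts)),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a 10x VDJ contig annotation table
#'
#' Parses the \code{filtered_contig_annotations.csv} dialect: one row per
#' assembled receptor contig with at least \code{barcode}, \code{chain},
#' \code{productive} and \code{umis} columns. The \code{productive} flag
#' accepts the \code{"True"/"true"/"TRUE"} spellings; any other value
#' (including \code{"None"}) is parsed as not productive. Chains outside
#' \{IGH, IGK, IGL, TRA, TRB\} (e.g. \code{"Multi"}) are retained but marked
#' unusable and excluded from the doublet rules.
#'
#' @param path CSV file path.
#' @return A \code{data.frame} with columns barcode, chain, productive, umis,
#'   v_gene, cdr3, usable.
#' @export
read_contigs <- function(path) {
  if (!file.exists(path)) stop("input path does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("barcode", "chain", "productive", "umis")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("contig table is missing required column(s): ",
         paste(missing, collapse = ", "))
  as_contig_table(
    data.frame(barcode = as.character(df$barcode),
               chain = as.character(df$chain),
               productive = parse_productive(df$productive),
               umis = as.integer(df$umis),
               v_gene = if ("v_gene" %in% names(df))
                 as.character(df$v_gene) else "",
               cdr3 = if ("cdr3" %in% names(df))
                 as.character(df$cdr3) else "",
               stringsAsFactors = FALSE))
}

parse_productive <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  tolower(as.character(x)) == "true"
}

vdj_chains <- c("IGH", "IGK", "IGL", "TRA", "TRB")

as_contig_table <- function(df) {
  stopifnot(all(c("barcode", "chain", "productive", "umis") %in% names(df)))
  if (any(df$umis < 0, na.rm = TRUE)) stop("contig UMI counts must be >= 0")
  df$usable <- df$chain %in% vdj_chains
  df
}

#' Write the per-droplet doublet call table as TSV
#'
#' @param calls data.frame as returned by \code{\link{predict.mltiplet}} or
#'   \code{\link{run_pipeline}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write per-barcode cluster labels
#'
#' Two-column TSV (barcode, cluster) with a header.
#'
#' @param path TSV file.
#' @return Named character vector (barcode to cluster).
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("label table needs two columns: barcode, cluster")
  stats::setNames(as.character(df[[2]]), df[[1]])
}

#' @rdname read_labels
#' @param labels named character vector (barcode to cluster).
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(barcode = names(labels), cluster = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
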