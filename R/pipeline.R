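#' Run the end-to-end doublet-detection pipeline
#'
#' Orchestrates the full method: read inputs, QC filter, obtain cell-type
#' labels (supplied or clustered + marker-annotated), flag CITE-seq and VDJ
#' doublets, assemble droplet features and module scores, build the training
#' set, fit the logistic GLM and predict doublet probabilities for every
#' droplet. Per-stage droplet counts are collected in a machine-readable run
#' report.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{expr}{\code{expression_matrix} or a path readable by
#'       \code{\link{read_expression}} (required).}
#'     \item{adt}{\code{adt_matrix} or MTX directory path (optional; without
#'       it the CITE-seq source is skipped).}
#'     \item{contigs}{contig table or CSV path (optional; without it the VDJ
#'       source is skipped).}
#'     \item{labels}{named barcode-to-cell-type vector or TSV path; when
#'       absent, droplets are clustered and clusters named via
#'       \code{marker_sets}.}
#'     \item{marker_sets}{named list of canonical marker genes per cell type,
#'       used to name clusters when \code{labels} is absent.}
#'     \item{qc}{list overriding \code{min_genes}, \code{min_umi},
#'       \code{max_pct_mito}, \code{mito_pattern}.}
#'     \item{antibody_map, exclusive_pairs, b_cell_types, t_cell_types,
#'       count_dual_tra, cutoff, covariates, ribo_pattern, sources}{tuning knobs
#'       with the package defaults.}
#'   }
#' @param seed integer seed (clustering, module-score controls).
#' @param out_dir optional directory; when given, the call table, features,
#'   labels, model JSON and run report JSON are written there.
#' @return List: \code{calls} (the per-droplet call table), \code{model}
#'   (the fitted \code{\link{mltiplet}}), \code{features}, \code{scores},
#'   \code{cell_types}, \code{report}.
#' @export
run_pipeline <- function(config, seed = 1, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- function(name, default = NULL)
    if (!is.null(config[[name]])) config[[name]] else default
  report <- list(seed = seed, stages = list())
  log_stage <- function(stage, n) {
    message(sprintf("[%s] %d droplets", stage, n))
    report$stages[[stage]] <<- n
  }

  # -- read ------------------------------------------------------------
  expr <- cfg("expr")
  if (is.null(expr)) stop("config must name an expression input")
  if (is.character(expr)) expr <- read_expression(expr,
                                                  sample_id = cfg("sample_id"))
  adt <- cfg("adt")
  if (is.character(adt)) {
    if (!file.exists(adt)) stop("ADT input path does not exist: ", adt)
    adt <- adt_matrix(read_mtx_dir(adt), sample_id = cfg("sample_id",
                                                         "sample1"))
  }
  contigs <- cfg("contigs")
  if (is.character(contigs)) contigs <- read_contigs(contigs)
  log_stage("read", ncol(expr$counts))

  # -- QC --------------------------------------------------------------
  qc <- cfg("qc", list())
  mito_pattern <- qc$mito_pattern %||% "^MT-"
  keep <- qc_filter(expr,
                    min_genes = qc$min_genes %||% 500,
                    min_umi = qc$min_umi %||% 1000,
                    max_pct_mito = qc$max_pct_mito %||% 25,
                    mito_pattern = mito_pattern)
  expr <- subset_barcodes(expr, keep)
  if (!is.null(adt))
    adt <- subset_barcodes(adt, intersect(keep, colnames(adt$counts)))
  log_stage("qc", length(keep))

  # -- labels ----------------------------------------------------------
  labels <- cfg("labels")
  if (is.character(labels) && length(labels) == 1L && file.exists(labels))
    labels <- read_labels(labels)
  if (is.null(labels)) {
    marker_sets <- cfg("marker_sets")
    if (is.null(marker_sets))
      stop("either labels or marker_sets must be supplied")
    clusters <- assign_clusters(expr, seed = seed,
                                n_pcs = cfg("n_pcs", 30),
                                resolution = cfg("resolution", 1.0))
    labels <- annotate_clusters(expr, clusters, marker_sets)
  }
  labels <- labels[intersect(names(labels), keep)]
  log_stage("labelled", length(labels))

  # -- CITE flags ------------------------------------------------------
  sources <- cfg("sources", c("vdj", "cite"))
  flags <- list()
  cite_calls <- NULL
  if ("cite" %in% sources && !is.null(adt)) {
    positivity <- fit_adt_positivity(
      clr_adt(adt), labels,
      antibody_map = cfg("antibody_map", default_antibody_map()))
    cite_calls <- flag_cite_doublets(
      positivity, pairs = cfg("exclusive_pairs", default_exclusive_pairs()))
    flags$cite <- cite_calls$barcode[cite_calls$cite_flag]
    log_stage("cite_flagged", length(flags$cite))
  }

  # -- VDJ flags -------------------------------------------------------
  vdj_calls <- NULL
  kept_contigs <- NULL
  if (!is.null(contigs)) {
    kept_contigs <- filter_contigs(contigs,
                                   min_umis = cfg("min_contig_umis", 6))
    if ("vdj" %in% sources) {
      vdj_calls <- identify_vdj_doublets(
        kept_contigs, cell_types = labels,
        b_cell_types = cfg("b_cell_types", "B cell"),
        t_cell_types = cfg("t_cell_types", "T cell"),
        count_dual_tra = isTRUE(cfg("count_dual_tra", FALSE)))
      flags$vdj <- vdj_calls$barcode[vdj_calls$vdj_flag]
      log_stage("vdj_flagged", length(flags$vdj))
    }
  }
  if (!length(flags))
    stop("no training source available (need ADT and/or contig input)")

  # -- features --------------------------------------------------------
  features <- droplet_features(expr, contigs = kept_contigs,
                               mito_pattern = mito_pattern,
                               ribo_pattern = cfg("ribo_pattern", "^RP[SL]"))
  de_markers <- marker_genes(expr, labels, top_n = cfg("top_n_markers", 5))
  de_markers <- de_markers[vapply(de_markers, length, integer(1)) > 0]
  scores <- module_scores(expr, de_markers, seed = seed)
  log_stage("features", nrow(features))

  # -- train / predict -------------------------------------------------
  training <- do.call(build_training_set, c(list(features$barcode), flags))
  model <- mltiplet(features, training, scores = scores,
                    cutoff = cfg("cutoff", 0.5),
                    covariates = cfg("covariates",
                                     c("mito_ribo_ratio", "clr_n_umi")))
  pred <- predict(model, features, scores = scores)
  log_stage("called", sum(pred$call))

  calls <- data.frame(
    barcode = pred$barcode,
    sample_id = features$sample_id,
    vdj_flag = pred$barcode %in% (flags$vdj %||% character(0)),
    vdj_subtype = if (!is.null(vdj_calls))
      vdj_calls$subtype[match(pred$barcode, vdj_calls$barcode)]
    else NA_character_,
    cite_flag = pred$barcode %in% (flags$cite %||% character(0)),
    cite_pairs = if (!is.null(cite_calls))
      cite_calls$cite_pairs[match(pred$barcode, cite_calls$barcode)]
    else NA_character_,
    training = pred$training,
    probability = pred$probability,
    call = pred$call,
    stringsAsFactors = FALSE)
  calls$vdj_subtype[is.na(calls$vdj_subtype)] <- "none"
  calls$cite_pairs[is.na(calls$cite_pairs)] <- ""

  report$n_training_positives <- length(model$training$positives)
  report$estimated_doublet_proportion <- estimate_doublet_proportion(calls)
  report$package_version <- as.character(utils::packageVersion("MLtiplet"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_calls(calls, file.path(out_dir, "doublet_calls.tsv"))
    utils::write.table(features, file.path(out_dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_labels(labels, file.path(out_dir, "labels.tsv"))
    write_model(model, file.path(out_dir, "model.json"))
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(calls = calls, model = model, features = features, scores = scores,
       cell_types = labels, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
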