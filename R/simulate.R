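#' Configuration for the synthetic multi-omic generator
#'
#' Defines the simulated study conditions: a PBMC-like mixture of B cells,
#' T cells and monocytes with negative-binomial RNA counts and planted
#' cell-type markers, bimodal ADT counts per antibody, lineage-consistent
#' VDJ chain capture, and an apoptotic subpopulation with elevated
#' mitochondrial / depressed ribosomal-protein fractions.
#'
#' @param n_cells named integer vector of cells per type.
#' @param n_background background (non-marker) genes.
#' @param markers_per_type planted marker genes per cell type.
#' @param marker_fold fold over-expression of a type's markers in that type.
#' @param depth_mean mean RNA library size (UMIs per healthy cell).
#' @param depth_sdlog log-normal spread of library size.
#' @param dispersion negative-binomial size parameter of the RNA counts.
#' @param mito_frac,ribo_frac expected mitochondrial / ribosomal-protein UMI
#'   fractions of healthy cells.
#' @param apoptotic_frac fraction of cells drawn as apoptotic.
#' @param apoptotic_mito,apoptotic_ribo mito / ribo fractions of apoptotic
#'   cells.
#' @param adt_pos_mean,adt_neg_mean NB means of positive / negative ADT
#'   populations.
#' @param vdj_capture probability a B (T) cell's receptor chains are
#'   captured.
#' @param sample_id sample name stamped on every droplet.
#' @param seed mandatory integer seed.
#' @return A \code{synth_config} list.
#' @export
synth_config <- function(n_cells = c("B cell" = 1500, "T cell" = 2500,
                                     "Monocyte" = 1000),
                         n_background = 150, markers_per_type = 15,
                         marker_fold = 10, depth_mean = 3000,
                         depth_sdlog = 0.15, dispersion = 10,
                         mito_frac = 0.05, ribo_frac = 0.25,
                         apoptotic_frac = 0.05, apoptotic_mito = 0.35,
                         apoptotic_ribo = 0.08,
                         adt_pos_mean = 120, adt_neg_mean = 8,
                         vdj_capture = 0.9, sample_id = "sim1", seed) {
  if (missing(seed)) stop("a seed is mandatory")
  probs <- c(apoptotic_frac, vdj_capture)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  fr <- c(mito_frac, ribo_frac, apoptotic_mito, apoptotic_ribo)
  if (any(fr <= 0) || mito_frac + ribo_frac >= 1 ||
      apoptotic_mito + apoptotic_ribo >= 1)
    stop("mito/ribo fractions must be positive and sum to < 1")
  cfg <- as.list(environment())
  cfg$probs <- NULL
  cfg$fr <- NULL
  structure(cfg, class = "synth_config")
}

mito_gene_names <- paste0("MT-", c("ND1", "ND2", "CO1", "CO2", "ATP6",
                                   "ND3", "ND4", "ND4L", "ND5", "ND6",
                                   "CYB", "ATP8", "CO3"))
ribo_gene_names <- c(paste0("RPS", 2:11), paste0("RPL", 3:12))

type_marker_pool <- list(
  "B cell" = c("CD19", "MS4A1", "CD79A", "CD79B", "IGHM", "IGHD", "TCL1A",
               "BANK1", "TNFRSF13B", "FCER2", "BLK", "VPREB3", "CD72",
               "BLNK", "PAX5"),
  "T cell" = c("CD3E", "CD3D", "CD3G", "CD2", "CD7", "TRAC", "TRBC2",
               "IL7R", "LCK", "CD27", "CD28", "THEMIS", "SKAP1", "LAT",
               "ITK"),
  "Monocyte" = c("CD14", "LYZ", "S100A8", "S100A9", "FCN1", "VCAN",
                 "FCGR3A", "CSF1R", "ITGAM", "CD68", "MNDA", "CEBPB",
                 "TYROBP", "FCER1G", "AIF1"))

# realistic CITE-seq panel width: the mapped markers plus activation
# markers and isotype controls. Panel width matters because the CLR margin
# is per droplet: with a handful of antibodies the positives themselves
# dominate the geometric mean and doublet CLR values compress.
adt_panel <- c("CD19", "CD3", "CD4", "CD8a", "CD56", "CD16", "CD14",
               "CD127", "CD25", "CD27", "CD28", "CD62L", "PD-1", "TIGIT",
               "IgG1", "IgG2a")

# which antibodies each simulated type stains positive for
adt_positive_map <- list(
  "B cell" = "CD19",
  "T cell" = c("CD3", "CD4", "CD127", "CD27", "CD28"),
  "Monocyte" = c("CD14", "CD16", "CD62L"))

#' Default antibody-to-reference map for the synthetic panel
#'
#' Links each antibody to its marker gene(s) and the cell types serving as
#' positive / negative reference populations for threshold fitting.
#'
#' @return Named list consumable by \code{\link{reference_populations}}.
#' @export
default_antibody_map <- function() {
  list(
    CD19 = list(genes = "CD19", pos = "B cell",
                neg = c("T cell", "Monocyte")),
    CD3 = list(genes = c("CD3E", "CD3D"), pos = "T cell",
               neg = c("B cell", "Monocyte")),
    CD4 = list(genes = "CD4", pos = "T cell", neg = "B cell"),
    CD127 = list(genes = "IL7R", pos = "T cell",
                 neg = c("B cell", "Monocyte")),
    CD14 = list(genes = "CD14", pos = "Monocyte",
                neg = c("B cell", "T cell")),
    CD16 = list(genes = "FCGR3A", pos = "Monocyte",
                neg = c("B cell", "T cell")))
}

#' Generate a fully synthetic multi-omic droplet dataset
#'
#' Draws RNA, ADT and VDJ modalities for singlet droplets according to the
#' configuration, deterministically per seed. B cells carry one productive
#' IGH plus one light chain (IGK or IGL); T cells one TRA plus one TRB;
#' monocytes carry no receptor contigs. A small admixture of non-productive
#' and low-UMI contigs exercises the contig filter. Apoptotic cells have
#' elevated mitochondrial and depressed ribosomal fractions and reduced
#' depth.
#'
#' @param config a \code{\link{synth_config}}.
#' @return List with elements \code{expr} (\code{expression_matrix}),
#'   \code{adt} (\code{adt_matrix}), \code{contigs} (contig table),
#'   \code{truth} (data.frame: barcode, cell_type, apoptotic, is_doublet,
#'   subtype, constituents) and \code{marker_sets} (the planted marker genes
#'   per type).
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  types <- names(config$n_cells)
  unknown <- setdiff(types, names(type_marker_pool))
  if (length(unknown))
    stop("no marker pool for cell type(s): ",
         paste(unknown, collapse = ", "))
  marker_sets <- lapply(type_marker_pool[types], utils::head,
                        config$markers_per_type)
  background <- sprintf("HKG%03d", seq_len(config$n_background))
  genes <- c(mito_gene_names, ribo_gene_names, unlist(marker_sets,
                                                      use.names = FALSE),
             background)

  n_total <- sum(config$n_cells)
  cell_type <- rep(types, config$n_cells)
  apoptotic <- stats::runif(n_total) < config$apoptotic_frac
  barcodes <- sprintf("CELL%05d-1", seq_len(n_total))

  # relative expression weights: one base draw shared across types,
  # markers boosted in their own type
  base_w <- stats::setNames(stats::rgamma(length(genes), 2, 2) + 0.05, genes)
  type_weights <- lapply(types, function(tp) {
    w <- base_w
    w[mito_gene_names] <- 0
    w[ribo_gene_names] <- 0
    for (other in types)
      w[marker_sets[[other]]] <- base_w[marker_sets[[other]]] *
        if (other == tp) config$marker_fold else 0.1
    w / sum(w)
  })
  names(type_weights) <- types

  frac_profile <- function(apo) {
    if (apo) c(config$apoptotic_mito, config$apoptotic_ribo)
    else c(config$mito_frac, config$ribo_frac)
  }
  depth <- stats::rlnorm(n_total, log(config$depth_mean),
                         config$depth_sdlog)
  depth[apoptotic] <- depth[apoptotic] * 0.6

  counts <- matrix(0L, length(genes), n_total,
                   dimnames = list(genes, barcodes))
  mito_split <- base_w[mito_gene_names] / sum(base_w[mito_gene_names])
  ribo_split <- base_w[ribo_gene_names] / sum(base_w[ribo_gene_names])
  for (i in seq_len(n_total)) {
    fr <- frac_profile(apoptotic[i])
    w <- type_weights[[cell_type[i]]] * (1 - sum(fr))
    w[mito_gene_names] <- fr[1] * mito_split
    w[ribo_gene_names] <- fr[2] * ribo_split
    counts[, i] <- stats::rnbinom(length(genes), mu = w * depth[i],
                                  size = config$dispersion)
  }

  adt_counts <- matrix(0L, length(adt_panel), n_total,
                       dimnames = list(adt_panel, barcodes))
  adt_scale <- stats::rlnorm(n_total, 0, 0.2)
  for (ab in adt_panel) {
    pos <- vapply(cell_type,
                  function(tp) ab %in% adt_positive_map[[tp]], logical(1))
    mu <- ifelse(pos, config$adt_pos_mean, config$adt_neg_mean) * adt_scale
    adt_counts[ab, ] <- stats::rnbinom(n_total, mu = mu, size = 10)
  }

  contigs <- draw_contigs(barcodes, cell_type, config)

  truth <- data.frame(barcode = barcodes, cell_type = cell_type,
                      apoptotic = apoptotic, is_doublet = FALSE,
                      subtype = "singlet", constituents = barcodes,
                      stringsAsFactors = FALSE)
  list(expr = expression_matrix(counts, sample_id = config$sample_id),
       adt = adt_matrix(adt_counts, sample_id = config$sample_id),
       contigs = contigs, truth = truth, marker_sets = marker_sets,
       config = config)
}

draw_contigs <- function(barcodes, cell_type, config) {
  rows <- list()
  contig_row <- function(bc, chain, productive = TRUE,
                         umis = 6L + stats::rpois(1, 20)) {
    v_pool <- switch(substr(chain, 1, 3),
                     IGH = paste0("IGHV", 1:6), IGK = paste0("IGKV", 1:4),
                     IGL = paste0("IGLV", 1:4), TRA = paste0("TRAV", 1:8),
                     TRB = paste0("TRBV", 1:8))
    data.frame(barcode = bc, chain = chain, productive = productive,
               umis = as.integer(umis), v_gene = sample(v_pool, 1),
               cdr3 = paste0("C", paste(sample(LETTERS[1:20],
                                               8, replace = TRUE),
                                        collapse = ""), "F"),
               stringsAsFactors = FALSE)
  }
  for (i in seq_along(barcodes)) {
    tp <- cell_type[i]
    bc <- barcodes[i]
    if (tp == "B cell" && stats::runif(1) < config$vdj_capture) {
      rows[[length(rows) + 1L]] <- contig_row(bc, "IGH")
      rows[[length(rows) + 1L]] <-
        contig_row(bc, sample(c("IGK", "IGL"), 1, prob = c(0.6, 0.4)))
      if (stats::runif(1) < 0.05)  # non-productive artifact
        rows[[length(rows) + 1L]] <- contig_row(bc, "IGH",
                                                productive = FALSE)
    } else if (tp == "T cell" && stats::runif(1) < config$vdj_capture) {
      rows[[length(rows) + 1L]] <- contig_row(bc, "TRB")
      rows[[length(rows) + 1L]] <- contig_row(bc, "TRA",
                                              umis = 6L + stats::rpois(1, 8))
      if (stats::runif(1) < 0.05)  # low-support artifact, filtered out
        rows[[length(rows) + 1L]] <- contig_row(bc, "TRB",
                                                umis = sample(1:5, 1))
    }
  }
  as_contig_table(do.call(rbind, rows))
}

#' Remove high-UMI droplets before spiking
#'
#' Cleaning step of the doublet-spiking protocol: droplets whose UMI count
#' strictly exceeds median + IQR (per sample; type-7 linear-interpolation
#' quartiles) are removed, so that pre-existing doublets do not contaminate
#' the simulated singlet pool.
#'
#' @param dataset a list with elements \code{expr} (+ optional \code{adt},
#'   \code{contigs}, \code{truth}) as produced by
#'   \code{\link{generate_synthetic}}, or a bare \code{expression_matrix}.
#' @return The dataset restricted to retained droplets.
#' @export
clean_base <- function(dataset) {
  bare <- inherits(dataset, "expression_matrix")
  expr <- if (bare) dataset else dataset$expr
  n_umi <- Matrix::colSums(expr$counts)
  keep <- rep(TRUE, length(n_umi))
  for (s in unique(expr$sample_id)) {
    idx <- expr$sample_id == s
    x <- n_umi[idx]
    cut <- stats::median(x) + stats::IQR(x)  # type-7 quartiles
    keep[idx] <- x <= cut
  }
  barcodes <- colnames(expr$counts)[keep]
  if (bare) return(subset_barcodes(expr, barcodes))
  subset_dataset(dataset, barcodes)
}

round_half_up <- function(x) floor(x + 0.5)

subset_dataset <- function(dataset, barcodes) {
  dataset$expr <- subset_barcodes(dataset$expr, barcodes)
  if (!is.null(dataset$adt))
    dataset$adt <- subset_barcodes(dataset$adt, barcodes)
  if (!is.null(dataset$contigs))
    dataset$contigs <- dataset$contigs[
      dataset$contigs$barcode %in% barcodes, , drop = FALSE]
  if (!is.null(dataset$truth))
    dataset$truth <- dataset$truth[
      match(barcodes, dataset$truth$barcode), , drop = FALSE]
  dataset
}

#' Spike simulated doublets into a base dataset
#'
#' Creates doublets by sampling cell pairs without replacement (within
#' sample) and summing their gene-expression, ADT and VDJ UMI counts; the
#' constituent droplets are removed and replaced by the merged droplet, whose
#' truth label combines the constituent cell types. The number of doublets is
#' chosen so that they make up exactly the nearest integer (halves rounded
#' up) to \code{proportion * N_out} of the \code{N_out} output droplets; when
#' the integer rounding admits no consistent count, up to two randomly chosen
#' base droplets are set aside first (recorded in the \code{"discarded"}
#' attribute of the result).
#'
#' @param dataset list as from \code{\link{generate_synthetic}} (pass through
#'   \code{\link{clean_base}} first).
#' @param proportion target doublet fraction of the output, in [0, 0.5).
#' @param seed integer seed.
#' @return The spiked dataset; \code{truth} records, per output droplet,
#'   \code{is_doublet}, the constituent barcodes and the combined
#'   \code{cell_type} label (\code{"A+B"}), and \code{subtype}
#'   (\code{homotypic}/\code{heterotypic}/\code{singlet}).
#' @export
spike_doublets <- function(dataset, proportion, seed) {
  stopifnot(proportion >= 0, proportion < 0.5)
  if (proportion == 0) return(dataset)
  set.seed(seed)
  expr <- dataset$expr
  n_base <- ncol(expr$counts)
  # d doublets consume 2d droplets and add d, so N_out = n_base - d;
  # pick d with round_half_up(p * N_out) == d. The integer step function can
  # oscillate around the crossing without a fixed point; setting aside a
  # base droplet or two always restores one.
  d <- NA_integer_
  discarded <- character(0)
  for (drop_n in 0:2) {
    n_eff <- n_base - drop_n
    d0 <- round_half_up(proportion * n_eff / (1 + proportion))
    for (cand in d0 + c(0, -1, 1, -2, 2)) {
      if (cand > 0 && round_half_up(proportion * (n_eff - cand)) == cand) {
        d <- cand
        break
      }
    }
    if (!is.na(d)) {
      if (drop_n > 0) {
        discarded <- sample(colnames(expr$counts), drop_n)
        dataset <- subset_dataset(dataset,
                                  setdiff(colnames(expr$counts), discarded))
        expr <- dataset$expr
        n_base <- ncol(expr$counts)
      }
      break
    }
  }
  if (is.na(d)) stop("no consistent doublet count at this proportion")
  if (2 * d > n_base) stop("not enough cells to spike at this proportion")

  samples <- expr$sample_id
  pairs <- matrix(NA_integer_, 0, 2)
  per_sample <- table(samples)
  alloc <- round(d * per_sample / n_base)
  alloc[length(alloc)] <- d - sum(alloc[-length(alloc)])
  for (s in names(per_sample)) {
    idx <- which(samples == s)
    take <- sample(idx, 2 * alloc[[s]])
    pairs <- rbind(pairs, matrix(take, ncol = 2))
  }

  barcodes <- colnames(expr$counts)
  dbl_bc <- sprintf("DBL%05d", seq_len(nrow(pairs)))
  c1 <- barcodes[pairs[, 1]]
  c2 <- barcodes[pairs[, 2]]

  new_expr <- expr$counts[, c1, drop = FALSE] +
    expr$counts[, c2, drop = FALSE]
  colnames(new_expr) <- dbl_bc
  keep <- setdiff(barcodes, c(c1, c2))
  counts <- cbind(expr$counts[, keep, drop = FALSE], new_expr)
  sample_id <- c(expr$sample_id[keep],
                 stats::setNames(expr$sample_id[c1], dbl_bc))
  dataset$expr <- expression_matrix(counts, sample_id = sample_id)

  if (!is.null(dataset$adt)) {
    new_adt <- dataset$adt$counts[, c1, drop = FALSE] +
      dataset$adt$counts[, c2, drop = FALSE]
    colnames(new_adt) <- dbl_bc
    dataset$adt <- adt_matrix(
      cbind(dataset$adt$counts[, keep, drop = FALSE], new_adt),
      sample_id = sample_id)
  }
  if (!is.null(dataset$contigs)) {
    map <- stats::setNames(c(keep, dbl_bc, dbl_bc), c(keep, c1, c2))
    ct <- dataset$contigs
    ct$barcode <- unname(map[ct$barcode])
    dataset$contigs <- ct
  }

  tr <- dataset$truth
  t1 <- tr$cell_type[match(c1, tr$barcode)]
  t2 <- tr$cell_type[match(c2, tr$barcode)]
  pair_label <- vapply(seq_along(t1), function(i)
    paste(sort(c(t1[i], t2[i])), collapse = "+"), character(1))
  dbl_truth <- data.frame(
    barcode = dbl_bc,
    cell_type = pair_label,
    apoptotic = tr$apoptotic[match(c1, tr$barcode)] |
      tr$apoptotic[match(c2, tr$barcode)],
    is_doublet = TRUE,
    subtype = ifelse(t1 == t2, "homotypic", "heterotypic"),
    constituents = paste(c1, c2, sep = ","),
    stringsAsFactors = FALSE)
  dataset$truth <- rbind(tr[match(keep, tr$barcode), ], dbl_truth)
  attr(dataset, "discarded") <- discarded
  dataset
}

#' Score doublet calls against simulation truth
#'
#' Per constituent-type combination with more than \code{min_group} planted
#' doublets: the fraction recovered (sensitivity); plus the overall
#' specificity on true singlets. Droplets absent from the call table (e.g.
#' removed by the QC filter before detection ran) are excluded from scoring,
#' since no call was made on them.
#'
#' @param calls data.frame with \code{barcode} and logical \code{call}.
#' @param truth truth table from \code{\link{spike_doublets}}.
#' @param min_group combinations with \code{<= min_group} planted doublets
#'   are excluded from the table.
#' @return List with \code{table} (data.frame: combination, subtype,
#'   n_planted, n_detected, sensitivity) and \code{specificity}.
#' @export
score_detection <- function(calls, truth, min_group = 5) {
  truth <- truth[truth$barcode %in% calls$barcode, , drop = FALSE]
  called <- calls$call[match(truth$barcode, calls$barcode)]
  dbl <- truth$is_doublet
  combos <- split(seq_len(nrow(truth))[dbl], truth$cell_type[dbl])
  rows <- lapply(names(combos), function(cmb) {
    idx <- combos[[cmb]]
    data.frame(combination = cmb,
               subtype = truth$subtype[idx[1]],
               n_planted = length(idx),
               n_detected = sum(called[idx]),
               sensitivity = mean(called[idx]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[tab$n_planted > min_group, , drop = FALSE]
  list(table = tab,
       specificity = if (any(!dbl)) mean(!called[!dbl]) else NA_real_)
}
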