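#' Filter VDJ contigs
#'
#' Retains productive contigs with at least \code{min_umis} UMIs (contigs with
#' fewer than 6 UMIs are removed by default) whose chain is one of IGH, IGK,
#' IGL, TRA, TRB.
#'
#' @param contigs contig table from \code{\link{read_contigs}}.
#' @param min_umis minimum UMI support (inclusive).
#' @return The retained rows.
#' @export
filter_contigs <- function(contigs, min_umis = 6) {
  contigs[contigs$usable & contigs$productive & contigs$umis >= min_umis, ,
          drop = FALSE]
}

#' Identify VDJ doublets with the chain co-capture rules
#'
#' A droplet is flagged as a VDJ-identified doublet/multiplet when any of
#' these rules fires on its filtered contigs:
#' \describe{
#'   \item{a}{a BCR chain (IGH and/or IGK/L) together with a TCR chain (TRA
#'     and/or TRB);}
#'   \item{b}{multiple BCRs: 2+ IGH chains, or 2+ light chains (IGK and IGL
#'     pooled);}
#'   \item{c}{multiple TCRs: 2+ TRB chains (2+ TRA chains count only when
#'     \code{count_dual_tra = TRUE}, since dual TCR-alpha cells are a normal
#'     biological state);}
#'   \item{d}{a BCR chain on a droplet whose cell type is not a B-cell type;}
#'   \item{e}{a TCR chain on a droplet whose cell type is not a T-cell type.}
#' }
#' Rules d and e need cell-type labels; unlabelled droplets skip them.
#' Heterotypic doublets are those firing a, d or e; droplets firing only b
#' (only c) are homotypic BCR (TCR) doublets. Identical chain+v_gene+cdr3
#' duplicates on one barcode are collapsed before counting.
#'
#' @param contigs filtered contig table (see \code{\link{filter_contigs}}).
#' @param cell_types optional named vector, barcode to cell-type name.
#' @param b_cell_types,t_cell_types cell-type names counting as B / T lineage
#'   for rules d and e; every name must exist in the label vocabulary.
#' @param count_dual_tra whether 2+ TRA chains alone fire rule c.
#' @return \code{data.frame} with one row per barcode carrying contigs:
#'   barcode, vdj_flag, rules (comma-joined subset of "a".."e"), subtype
#'   (heterotypic / homotypic_BCR / homotypic_TCR / none), n_umi_vdj.
#' @export
identify_vdj_doublets <- function(contigs, cell_types = NULL,
                                  b_cell_types = "B cell",
                                  t_cell_types = "T cell",
                                  count_dual_tra = FALSE) {
  if (!is.null(cell_types)) {
    vocab <- unique(cell_types)
    unknown <- setdiff(c(b_cell_types, t_cell_types), vocab)
    if (length(unknown))
      stop("cell type(s) not present in the labels: ",
           paste(unknown, collapse = ", "))
  }
  # collapse cell-ranger duplicate contigs (same chain + V gene + CDR3)
  key <- paste(contigs$barcode, contigs$chain, contigs$v_gene, contigs$cdr3,
               sep = "\r")
  contigs <- contigs[!duplicated(key), , drop = FALSE]
  barcodes <- unique(contigs$barcode)
  count_chain <- function(ch) {
    tab <- table(factor(contigs$barcode[contigs$chain %in% ch],
                        levels = barcodes))
    as.integer(tab)
  }
  n_igh <- count_chain("IGH")
  n_light <- count_chain(c("IGK", "IGL"))
  n_tra <- count_chain("TRA")
  n_trb <- count_chain("TRB")
  umis <- tapply(contigs$umis, factor(contigs$barcode, levels = barcodes),
                 sum)
  type <- if (is.null(cell_types)) rep(NA_character_, length(barcodes))
  else unname(cell_types[barcodes])

  has_bcr <- n_igh + n_light >= 1
  has_tcr <- n_tra + n_trb >= 1
  rule_a <- has_bcr & has_tcr
  rule_b <- n_igh >= 2 | n_light >= 2
  rule_c <- n_trb >= 2 | (count_dual_tra & n_tra >= 2)
  rule_d <- has_bcr & !is.na(type) & !(type %in% b_cell_types)
  rule_e <- has_tcr & !is.na(type) & !(type %in% t_cell_types)

  fired <- cbind(a = rule_a, b = rule_b, c = rule_c, d = rule_d, e = rule_e)
  flag <- rowSums(fired) > 0
  heterotypic <- rule_a | rule_d | rule_e
  subtype <- rep("none", length(barcodes))
  subtype[flag & !heterotypic & rule_b] <- "homotypic_BCR"
  subtype[flag & !heterotypic & rule_c] <- "homotypic_TCR"
  subtype[heterotypic] <- "heterotypic"
  data.frame(
    barcode = barcodes,
    vdj_flag = unname(flag),
    rules = apply(fired, 1, function(f)
      paste(colnames(fired)[f], collapse = ",")),
    subtype = subtype,
    n_umi_vdj = as.integer(umis),
    stringsAsFactors = FALSE)
}
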