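#' One-dimensional linear-discriminant threshold
#'
#' Decision boundary of a two-class linear discriminant with pooled variance:
#' t = (mu_pos + mu_neg)/2 + sigma^2 * log(prior_neg/prior_pos) /
#' (mu_pos - mu_neg). With equal priors this is the midpoint of the class
#' means. Used to set the per-antibody CITE-seq positivity cutoff from
#' reference populations with known high and low expression.
#'
#' @param values_pos,values_neg numeric samples from the positive and
#'   negative reference populations (each of size >= 10).
#' @param prior_pos,prior_neg class priors (default equal; reference
#'   populations have arbitrary relative sizes).
#' @param eps minimum mean separation; below it the antibody cannot be
#'   thresholded and an error of class \code{"degenerate_separation"} is
#'   raised.
#' @return The threshold (same units as the inputs).
#' @export
lda_threshold <- function(values_pos, values_neg,
                          prior_pos = 0.5, prior_neg = 0.5, eps = 1e-8) {
  if (length(values_pos) < 10 || length(values_neg) < 10)
    stop("each reference population needs at least 10 values")
  m_pos <- mean(values_pos)
  m_neg <- mean(values_neg)
  if (abs(m_pos - m_neg) < eps)
    stop(structure(
      list(message = "reference populations are not separated",
           call = sys.call()),
      class = c("degenerate_separation", "error", "condition")))
  n_pos <- length(values_pos)
  n_neg <- length(values_neg)
  s2 <- ((n_pos - 1) * stats::var(values_pos) +
         (n_neg - 1) * stats::var(values_neg)) / (n_pos + n_neg - 2)
  (m_pos + m_neg) / 2 + s2 * log(prior_neg / prior_pos) / (m_pos - m_neg)
}

#' Reference populations per antibody
#'
#' Looks up, for each antibody in the map, the barcodes of the labelled cell
#' types declared positive and negative for it (e.g. T cells as the CD3
#' positive reference; B cells and myeloid cells as the negative one).
#'
#' @param cell_types named vector, barcode to cell-type name.
#' @param antibody_map named list: antibody to
#'   \code{list(genes=..., pos=..., neg=...)} where \code{pos}/\code{neg} are
#'   cell-type names.
#' @param panel antibodies to resolve (default: all in the map). Antibodies
#'   absent from the map are skipped with a warning.
#' @return Named list: antibody to \code{list(pos=barcodes, neg=barcodes)}.
#' @export
reference_populations <- function(cell_types, antibody_map,
                                  panel = names(antibody_map)) {
  vocab <- unique(cell_types)
  out <- list()
  for (ab in panel) {
    if (is.null(antibody_map[[ab]])) {
      warning("antibody ", ab, " missing from the map; skipped")
      next
    }
    spec <- antibody_map[[ab]]
    unknown <- setdiff(c(spec$pos, spec$neg), vocab)
    if (length(unknown))
      stop("cell type(s) not present in the labels: ",
           paste(unknown, collapse = ", "))
    out[[ab]] <- list(
      pos = names(cell_types)[cell_types %in% spec$pos],
      neg = names(cell_types)[cell_types %in% spec$neg])
  }
  out
}

#' Sensitivity of an antibody's positivity calls
#'
#' Fraction of the gene-expression-positive reference cells that were called
#' ADT-positive. The antibody is usable only when this exceeds
#' \code{min_sensitivity} (strictly).
#'
#' @param positive named logical vector of per-barcode positivity for one
#'   antibody.
#' @param pos_barcodes the positive reference barcodes.
#' @return The sensitivity in [0, 1]; \code{NaN} when the reference is empty.
#' @export
probe_sensitivity <- function(positive, pos_barcodes) {
  pos_barcodes <- intersect(pos_barcodes, names(positive))
  if (!length(pos_barcodes)) return(NaN)
  mean(positive[pos_barcodes])
}

#' Fit per-antibody positivity thresholds
#'
#' For every antibody with a reference definition: an LDA threshold on the
#' CLR values of the positive vs negative reference populations, positivity
#' calls (CLR strictly above threshold) for all droplets, the sensitivity on
#' the positive reference, and a usability flag (sensitivity strictly above
#' \code{min_sensitivity}). Antibodies with degenerate separation or an empty
#' reference are marked unusable.
#'
#' @param adt an \code{\link{adt_matrix}} (CLR computed on the fly if absent).
#' @param cell_types named vector, barcode to cell-type name.
#' @param antibody_map see \code{\link{reference_populations}}.
#' @param min_sensitivity usability cutoff (strict).
#' @param prior_pos LDA prior for the positive class.
#' @return Object of class \code{adt_positivity}: list with
#'   \code{thresholds}, \code{sensitivities}, \code{usable} (named per
#'   antibody) and \code{positive} (antibody x barcode logical matrix).
#' @export
fit_adt_positivity <- function(adt, cell_types, antibody_map,
                               min_sensitivity = 0.7, prior_pos = 0.5) {
  if (is.null(adt$clr)) adt <- clr_adt(adt)
  refs <- reference_populations(cell_types, antibody_map,
                                panel = intersect(rownames(adt$clr),
                                                  names(antibody_map)))
  abs_ <- names(refs)
  thresholds <- stats::setNames(rep(NA_real_, length(abs_)), abs_)
  sens <- stats::setNames(rep(NaN, length(abs_)), abs_)
  positive <- matrix(FALSE, length(abs_), ncol(adt$clr),
                     dimnames = list(abs_, colnames(adt$clr)))
  for (ab in abs_) {
    pos_bc <- intersect(refs[[ab]]$pos, colnames(adt$clr))
    neg_bc <- intersect(refs[[ab]]$neg, colnames(adt$clr))
    if (length(pos_bc) < 10 || length(neg_bc) < 10) next
    t_ab <- tryCatch(
      lda_threshold(adt$clr[ab, pos_bc], adt$clr[ab, neg_bc],
                    prior_pos = prior_pos, prior_neg = 1 - prior_pos),
      degenerate_separation = function(e) NA_real_)
    if (is.na(t_ab)) next
    thresholds[ab] <- t_ab
    positive[ab, ] <- adt$clr[ab, ] > t_ab
    sens[ab] <- probe_sensitivity(positive[ab, ], pos_bc)
  }
  usable <- !is.na(thresholds) & !is.nan(sens) & sens > min_sensitivity
  structure(list(thresholds = thresholds, sensitivities = sens,
                 usable = usable, positive = positive,
                 min_sensitivity = min_sensitivity),
            class = "adt_positivity")
}

#' @export
print.adt_positivity <- function(x, ...) {
  cat(sprintf("adt_positivity: %d antibodies (%d usable), %d droplets\n",
              length(x$thresholds), sum(x$usable), ncol(x$positive)))
  invisible(x)
}

#' Default mutually exclusive CITE-seq marker pairs (human PBMC)
#'
#' Surface-marker pairs that no single cell co-expresses at high level, so
#' co-positivity marks a mixed-cell droplet. The duplicated CD19+CD56 entry
#' of the source list is deduplicated.
#'
#' @return Two-column character matrix of unordered pairs.
#' @export
default_exclusive_pairs <- function() {
  rbind(c("CD19", "CD3"), c("CD19", "CD4"), c("CD19", "CD8a"),
        c("CD19", "CD56"), c("CD19", "CD16"), c("CD19", "CD14"),
        c("CD19", "CD127"), c("CD4", "CD16"), c("CD127", "CD16"))
}

#' Flag CITE-seq doublets from mutually exclusive co-positivity
#'
#' A droplet is flagged when it is positive for both members of at least one
#' mutually exclusive antibody pair; every triggering pair is recorded. Pairs
#' referencing an unusable antibody are dropped with a warning.
#'
#' @param positivity an \code{adt_positivity} object.
#' @param pairs two-column character matrix of antibody pairs
#'   (default \code{\link{default_exclusive_pairs}()}).
#' @return \code{data.frame}: barcode, cite_flag, cite_pairs (comma-joined
#'   "A+B" strings, "" when unflagged).
#' @export
flag_cite_doublets <- function(positivity, pairs = default_exclusive_pairs()) {
  stopifnot(inherits(positivity, "adt_positivity"))
  pairs <- matrix(as.character(pairs), ncol = 2)
  if (any(pairs[, 1] == pairs[, 2])) stop("self-pairs are not allowed")
  in_panel <- pairs[, 1] %in% rownames(positivity$positive) &
    pairs[, 2] %in% rownames(positivity$positive)
  if (any(!in_panel)) {
    warning("dropping pair(s) outside the panel: ",
            paste(apply(pairs[!in_panel, , drop = FALSE], 1, paste,
                        collapse = "+"), collapse = ", "))
    pairs <- pairs[in_panel, , drop = FALSE]
  }
  ok <- positivity$usable[pairs[, 1]] & positivity$usable[pairs[, 2]]
  if (any(!ok)) {
    warning("dropping pair(s) with unusable antibody: ",
            paste(apply(pairs[!ok, , drop = FALSE], 1, paste,
                        collapse = "+"), collapse = ", "))
    pairs <- pairs[ok, , drop = FALSE]
  }
  barcodes <- colnames(positivity$positive)
  hits <- matrix(FALSE, length(barcodes), nrow(pairs))
  if (nrow(pairs))
    for (i in seq_len(nrow(pairs)))
      hits[, i] <- positivity$positive[pairs[i, 1], ] &
        positivity$positive[pairs[i, 2], ]
  pair_names <- if (nrow(pairs)) paste(pairs[, 1], pairs[, 2], sep = "+")
  else character(0)
  data.frame(
    barcode = barcodes,
    cite_flag = rowSums(hits) > 0,
    cite_pairs = apply(hits, 1, function(h)
      paste(pair_names[h], collapse = ",")),
    stringsAsFactors = FALSE)
}
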