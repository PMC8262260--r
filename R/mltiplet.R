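#' Assemble a doublet training set
#'
#' Positives are the union of the flagged barcodes across the supplied
#' identification sources (VDJ rules, CITE-seq co-positivity, or any external
#' per-barcode call column such as a DoubletFinder call); negatives are every
#' other droplet — a set enriched for true singlets, not guaranteed pure.
#'
#' @param barcodes the universe of droplet barcodes.
#' @param ... one or more named character vectors of flagged barcodes
#'   (e.g. \code{vdj = ..., cite = ...}).
#' @return Object of class \code{training_set}: list with \code{positives},
#'   \code{negatives} and \code{sources} (named list of per-source flags).
#' @export
build_training_set <- function(barcodes, ...) {
  sources <- list(...)
  if (!length(sources)) stop("at least one flag source is required")
  sources <- lapply(sources, function(s) intersect(s, barcodes))
  positives <- unique(unlist(sources, use.names = FALSE))
  if (!length(positives)) stop("no identified doublets in any source")
  negatives <- setdiff(barcodes, positives)
  if (!length(negatives))
    stop("every droplet is flagged; no negatives remain")
  structure(list(positives = positives, negatives = negatives,
                 sources = sources),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("training_set: %d positives (%s), %d negatives\n",
              length(x$positives),
              paste(sprintf("%s=%d", names(x$sources),
                            vapply(x$sources, length, integer(1))),
                    collapse = ", "),
              length(x$negatives)))
  invisible(x)
}

#' Two-standard-deviation outlier trim
#'
#' Keeps a barcode only when every listed variable lies within 2 standard
#' deviations of that variable's mean, the mean and SD being computed on the
#' group being trimmed. Applied independently to the positive and negative
#' training groups before fitting.
#'
#' @param features feature table (\code{\link{droplet_features}} output,
#'   possibly with module-score columns appended).
#' @param barcodes the group to trim.
#' @param vars variables entering the trim.
#' @return The retained barcodes.
#' @export
trim_2sd <- function(features, barcodes,
                     vars = c("mito_ribo_ratio", "clr_n_genes",
                              "clr_n_umi", "clr_n_umi_vdj")) {
  vars <- intersect(vars, names(features))
  rows <- features[match(barcodes, features$barcode), vars, drop = FALSE]
  keep <- rep(TRUE, length(barcodes))
  for (v in vars) {
    x <- rows[[v]]
    mu <- mean(x)
    sd_v <- stats::sd(x)
    if (!is.finite(sd_v) || sd_v == 0) next
    keep <- keep & abs(x - mu) <= 2 * sd_v
  }
  if (!any(keep)) stop("2-SD trimming removed every barcode in the group")
  barcodes[keep]
}

#' Fit the MLtiplet doublet classifier
#'
#' The core model: a logistic generalized linear model of
#' identified-doublet status on droplet features — the mito-ribo ratio, the
#' per-sample CLR-transformed UMI covariates and per-cell-type module scores.
#' Both training groups are first trimmed to within 2 SD of their group means
#' on the carried covariates, then the GLM is fitted by maximum likelihood
#' and used to score every droplet with a doublet/multiplet probability.
#' Under perfect separation the fit falls back to a ridge-stabilised
#' logistic regression (penalty 1e-4) with a warning.
#'
#' @param features feature table from \code{\link{droplet_features}}.
#' @param training a \code{training_set} (see
#'   \code{\link{build_training_set}}) or a character vector of positive
#'   barcodes.
#' @param scores optional module-score matrix (barcodes x cell types) joined
#'   as additional covariates.
#' @param cutoff probability above which (strictly) a droplet is called.
#' @param trim apply the 2-SD trim before fitting.
#' @param covariates count covariates entering the design matrix. The
#'   default is the mito-ribo ratio and the CLR nUMI count. Covariates that
#'   encode the labelling mechanism itself — above all the VDJ UMI count,
#'   which every VDJ- or CITE-identified training doublet carries but
#'   receptor-less doublets (e.g. monocyte+monocyte) never do — must stay
#'   out of the model for it to generalise across lineages; they remain in
#'   the 2-SD trim, which is where they inform the fit.
#' @return Object of class \code{mltiplet}: coefficients, feature names,
#'   cutoff, training bookkeeping and (when the unpenalised path succeeded)
#'   the underlying \code{glm} fit.
#' @seealso \code{\link{predict.mltiplet}}, \code{\link{summary.mltiplet}}
#' @export
mltiplet <- function(features, training, scores = NULL, cutoff = 0.5,
                     trim = TRUE,
                     covariates = c("mito_ribo_ratio", "clr_n_umi")) {
  if (!inherits(training, "training_set"))
    training <- build_training_set(features$barcode, flags = training)
  covars <- covariates
  X <- design_matrix(features, scores, covars)
  pos <- training$positives
  neg <- training$negatives
  if (trim) {
    pos <- trim_2sd(features, pos)
    neg <- trim_2sd(features, neg)
  }
  train_bc <- c(pos, neg)
  y <- as.numeric(train_bc %in% training$positives)
  Xt <- X[train_bc, , drop = FALSE]
  # drop collinear columns
  qr_x <- qr(cbind(1, Xt))
  if (qr_x$rank < ncol(Xt) + 1L) {
    drop_idx <- qr_x$pivot[-seq_len(qr_x$rank)] - 1L
    drop_idx <- drop_idx[drop_idx > 0]
    warning("dropping collinear feature(s): ",
            paste(colnames(Xt)[drop_idx], collapse = ", "))
    Xt <- Xt[, -drop_idx, drop = FALSE]
    X <- X[, colnames(Xt), drop = FALSE]
  }
  df <- data.frame(.y = y, Xt, check.names = FALSE)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated) {
    warning("(quasi-)separation detected; using a ridge-stabilised fit")
    rfit <- glmnet::glmnet(Xt, y, family = "binomial", alpha = 0,
                           lambda = 1e-4, standardize = FALSE)
    beta <- c(`(Intercept)` = as.numeric(rfit$a0),
              stats::setNames(as.numeric(rfit$beta), rownames(rfit$beta)))
    glm_fit <- NULL
  } else {
    beta <- stats::coef(fit)
    names(beta) <- c("(Intercept)", colnames(Xt))
    glm_fit <- fit
  }
  structure(list(coefficients = beta,
                 feature_names = colnames(Xt),
                 cutoff = cutoff,
                 training = training,
                 trimmed = list(positives = pos, negatives = neg),
                 trim = trim, covariates = covars,
                 ridge = separated, glm = glm_fit),
            class = "mltiplet")
}

design_matrix <- function(features, scores, covars) {
  missing <- setdiff(covars, names(features))
  if (length(missing))
    stop("feature table is missing column(s): ",
         paste(missing, collapse = ", "))
  X <- as.matrix(features[, covars, drop = FALSE])
  rownames(X) <- features$barcode
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    if (!all(features$barcode %in% rownames(scores)))
      stop("module-score matrix does not cover all barcodes")
    X <- cbind(X, scores[features$barcode, , drop = FALSE])
  }
  X
}

#' Predict doublet probabilities and calls
#'
#' Scores droplets with the fitted model: probability via the inverse logit
#' of the linear predictor, a call when the probability strictly exceeds the
#' cutoff. Droplets in the identified-doublet training set are always
#' reported as doublets and tagged \code{training = TRUE}.
#'
#' @param object a fitted \code{\link{mltiplet}} model.
#' @param features feature table with the same schema used at fit time.
#' @param scores module-score matrix if one was used at fit time.
#' @param cutoff override the stored classification cutoff.
#' @param ... unused.
#' @return \code{data.frame}: barcode, probability, training, call.
#' @export
predict.mltiplet <- function(object, features, scores = NULL,
                             cutoff = object$cutoff, ...) {
  covars <- setdiff(object$feature_names,
                    if (is.null(scores)) character(0) else colnames(scores))
  X <- design_matrix(features, scores, covars)
  missing <- setdiff(object$feature_names, colnames(X))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  X <- X[, object$feature_names, drop = FALSE]
  eta <- drop(cbind(1, X) %*% object$coefficients)
  prob <- stats::plogis(eta)
  training <- features$barcode %in% object$training$positives
  data.frame(barcode = features$barcode,
             probability = unname(prob),
             training = training,
             call = training | prob > cutoff,
             stringsAsFactors = FALSE)
}

#' Estimated doublet proportion
#'
#' (training positives + predicted positives) / total droplets, from a call
#' table.
#'
#' @param calls output of \code{\link{predict.mltiplet}} (or the pipeline's
#'   call table with a logical \code{call} column).
#' @return Fraction in [0, 1].
#' @export
estimate_doublet_proportion <- function(calls) {
  if (!nrow(calls)) return(0)
  mean(calls$call)
}

#' @export
print.mltiplet <- function(x, ...) {
  cat("MLtiplet doublet classifier (logistic GLM)\n")
  cat(sprintf("  training: %d positives / %d negatives after %s\n",
              length(x$trimmed$positives), length(x$trimmed$negatives),
              if (x$trim) "2-SD trim" else "no trim"))
  cat(sprintf("  features: %s\n", paste(x$feature_names, collapse = ", ")))
  cat(sprintf("  cutoff: %g%s\n", x$cutoff,
              if (x$ridge) "  (ridge-stabilised fit)" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.mltiplet <- function(object, ...) object$coefficients

#' @export
summary.mltiplet <- function(object, ...) {
  print(object)
  if (!is.null(object$glm)) {
    cat("\nGLM coefficient table:\n")
    stats::printCoefmat(summary(object$glm)$coefficients)
  }
  invisible(object)
}

#' @export
residuals.mltiplet <- function(object, ...) {
  if (is.null(object$glm))
    stop("residuals are unavailable for the ridge-stabilised fit")
  stats::residuals(object$glm, ...)
}

#' Histogram of predicted doublet probabilities
#'
#' @param x a fitted \code{mltiplet} model.
#' @param features,scores data to score (defaults to nothing; required).
#' @param ... passed to \code{hist}.
#' @export
plot.mltiplet <- function(x, features, scores = NULL, ...) {
  p <- predict(x, features, scores)$probability
  graphics::hist(p, breaks = 50, main = "doublet/multiplet probability",
                 xlab = "probability", ...)
  graphics::abline(v = x$cutoff, col = "red", lty = 2)
  invisible(x)
}

#' Persist / restore a fitted model as JSON
#'
#' Stores the coefficient vector, feature order and cutoff — everything
#' needed to score new droplets.
#'
#' @param object a fitted \code{mltiplet} model.
#' @param path JSON file.
#' @return \code{path} (write) / an \code{mltiplet} object (read).
#' @export
write_model <- function(object, path) {
  jsonlite::write_json(
    list(coefficients = as.list(object$coefficients),
         feature_names = object$feature_names,
         cutoff = object$cutoff, ridge = object$ridge),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = unlist(obj$coefficients),
                 feature_names = obj$feature_names,
                 cutoff = obj$cutoff,
                 training = list(positives = character(0)),
                 trimmed = list(positives = character(0),
                                negatives = character(0)),
                 trim = NA, covariates = NULL, ridge = obj$ridge, glm = NULL),
            class = "mltiplet")
}
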