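#' Fit a two-component univariate Gaussian mixture
#'
#' Expectation-maximisation with \code{n_init} seeded random restarts; the
#' fit with the best log-likelihood is kept, so the result is deterministic
#' given \code{seed}. Used on the mito-ribo ratio to separate healthy from
#' apoptotic/low-quality droplets (and, on log detected-gene counts, to set a
#' data-driven gene-count threshold).
#'
#' @param values numeric vector (length >= 50, nonzero variance).
#' @param seed integer seed for the restarts.
#' @param n_init number of random restarts.
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per restart.
#' @return Object of class \code{gmm2_fit}: weights, means (ascending),
#'   variances, loglik, converged, threshold (the mixture-density local
#'   minimum, NA when undefined).
#' @export
fit_gmm2 <- function(values, seed = 1, n_init = 10, tol = 1e-6,
                     max_iter = 500) {
  values <- values[is.finite(values)]
  if (length(values) < 50)
    stop("GMM fitting needs at least 50 values")
  if (stats::var(values) == 0)
    stop("values have zero variance; no mixture to fit")
  best <- NULL
  for (r in seq_len(n_init)) {
    set.seed(seed + r - 1L)
    fit <- em_gmm2(values, mu = sample(values, 2), tol = tol,
                   max_iter = max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged)
    warning("EM did not converge in any restart")
  ord <- order(best$mu)
  out <- structure(list(weights = best$pi[ord], means = best$mu[ord],
                        variances = best$sigma2[ord], loglik = best$loglik,
                        converged = best$converged, threshold = NA_real_),
                   class = "gmm2_fit")
  out$threshold <- tryCatch(mixture_local_min(out),
                            error = function(e) NA_real_)
  out
}

em_gmm2 <- function(x, mu, tol, max_iter) {
  n <- length(x)
  pi_k <- c(0.5, 0.5)
  sigma2 <- rep(stats::var(x), 2)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- pi_k[1] * stats::dnorm(x, mu[1], sqrt(sigma2[1]))
    d2 <- pi_k[2] * stats::dnorm(x, mu[2], sqrt(sigma2[2]))
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    n1 <- sum(g)
    n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break  # component collapsed
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    sigma2 <- c(sum(g * (x - mu[1])^2) / n1,
                sum((1 - g) * (x - mu[2])^2) / n2)
    sigma2 <- pmax(sigma2, 1e-10)
    pi_k <- c(n1, n2) / n
  }
  list(pi = pi_k, mu = mu, sigma2 = sigma2, loglik = ll_old,
       converged = converged)
}

#' @export
print.gmm2_fit <- function(x, ...) {
  cat(sprintf(paste0("gmm2_fit: weights (%.3f, %.3f), means (%.4f, %.4f),",
                     " sd (%.4f, %.4f)\n  threshold %.4f, %s\n"),
              x$weights[1], x$weights[2], x$means[1], x$means[2],
              sqrt(x$variances[1]), sqrt(x$variances[2]), x$threshold,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# mixture density of a gmm2_fit
dgmm2 <- function(x, fit) {
  fit$weights[1] * stats::dnorm(x, fit$means[1], sqrt(fit$variances[1])) +
    fit$weights[2] * stats::dnorm(x, fit$means[2], sqrt(fit$variances[2]))
}

#' Local minimum of the mixture density between the component means
#'
#' Grid argmin of the fitted density on [mean1, mean2], refined by
#' golden-section search to 1e-6. This valley is the data-driven threshold
#' separating the two populations. Errors when the density is monotone on the
#' interval (no interior minimum), which indicates the data are effectively
#' unimodal.
#'
#' @param fit a converged \code{gmm2_fit} with separated means.
#' @param grid_step spacing of the initial grid.
#' @return The threshold, strictly between the component means.
#' @export
mixture_local_min <- function(fit, grid_step = 1e-3) {
  if (!fit$converged) stop("mixture fit did not converge")
  lo <- fit$means[1]
  hi <- fit$means[2]
  if (hi - lo <= 2 * grid_step)
    stop("component means are not separated")
  grid <- seq(lo, hi, by = grid_step)
  dens <- dgmm2(grid, fit)
  i <- which.min(dens)
  if (i == 1L || i == length(grid))
    stop("mixture density is monotone between the means; ",
         "the data look unimodal")
  stats::optimize(dgmm2, fit = fit,
                  interval = c(grid[i - 1], grid[i + 1]),
                  tol = 1e-6)$minimum
}

#' Flag putative apoptotic / low-quality droplets
#'
#' A droplet is flagged when its mito-ribo ratio is strictly above the
#' threshold (typically the \code{\link{mixture_local_min}} of a
#' \code{\link{fit_gmm2}} on the ratios).
#'
#' @param features feature table from \code{\link{droplet_features}}, or a
#'   numeric vector of mito-ribo ratios.
#' @param threshold the ratio cutoff.
#' @return Named logical vector per barcode (unnamed for a bare vector).
#' @export
flag_dying <- function(features, threshold) {
  if (is.data.frame(features)) {
    stats::setNames(features$mito_ribo_ratio > threshold, features$barcode)
  } else {
    features > threshold
  }
}
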