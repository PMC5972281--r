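# Case-study diagnostics: positive-definiteness screening of moment
# matrices and Mahalanobis-distance outlier detection with refit.

#' Positive-definiteness check via eigenvalues
#'
#' The principal-component check of an input moment matrix: the matrix is
#' positive definite iff all eigenvalues exceed the tolerance. Slightly
#' asymmetric input (numerical noise below 1e-8) is symmetrized with a
#' warning; larger asymmetry is an error.
#'
#' @param m Symmetric square matrix.
#' @param tol Positivity tolerance for the smallest eigenvalue.
#' @return List with `positive_definite` (logical) and `eigenvalues`
#'   (decreasing).
#' @export
is_positive_definite <- function(m, tol = 1e-10) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("'m' must be square")
  asym <- max(abs(m - t(m)))
  if (asym >= 1e-8) stop("'m' is not symmetric (max asymmetry ", asym, ")")
  if (asym > 0) {
    warning("symmetrizing input with max asymmetry ", signif(asym, 3))
    m <- (m + t(m)) / 2
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  list(positive_definite = min(ev) > tol, eigenvalues = ev)
}

#' Mahalanobis-distance outlier screening
#'
#' Squared Mahalanobis distances of each case from the multivariate mean,
#' \eqn{(x_i - \bar x)' S^{-1} (x_i - \bar x)} with the `n - 1` sample
#' covariance, flagged against the upper-`alpha` quantile of the
#' chi-square distribution with `p` degrees of freedom. This computes the
#' leverage screening directly, without the auxiliary random criterion
#' variable sometimes used to obtain the same distances from regression
#' software.
#'
#' @param x Data matrix or `"cfa_sample"`.
#' @param alpha Per-case significance level (default 0.05, unadjusted).
#' @return A `"cfa_outliers"` list: `distances`, `flagged` (row indices),
#'   `cutoff`, `alpha`, `p`, `n`.
#' @export
mahalanobis_outliers <- function(x, alpha = 0.05) {
  xm <- as.matrix(unclass(x))
  attr(xm, "model") <- NULL
  n <- nrow(xm); p <- ncol(xm)
  if (n <= p) stop("need more cases than variables")
  S <- stats::cov(xm)
  pd <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(pd))
    stop("singular sample covariance; run is_positive_definite() on it ",
         "to inspect the eigenvalues")
  d2 <- stats::mahalanobis(xm, colMeans(xm), S)
  cutoff <- stats::qchisq(1 - alpha, df = p)
  structure(list(distances = d2, flagged = which(d2 > cutoff),
                 cutoff = cutoff, alpha = alpha, p = p, n = n),
            class = "cfa_outliers")
}

#' @export
print.cfa_outliers <- function(x, ...) {
  cat(sprintf("Mahalanobis screening: %d of %d cases beyond chi-square(%d) cutoff %.3f (alpha = %.2f)\n",
              length(x$flagged), x$n, x$p, x$cutoff, x$alpha))
  if (length(x$flagged)) cat("  flagged cases:",
                             paste(utils::head(x$flagged, 20), collapse = " "),
                             if (length(x$flagged) > 20) "...", "\n")
  invisible(x)
}

#' Refit the model after removing flagged outliers
#'
#' Drops the flagged cases, recomputes the sample moments, refits the
#' one-factor model and rescores congruence against the population
#' loadings. With nothing flagged the refit equals the original fit.
#'
#' @param x Data matrix or `"cfa_sample"` the screening was run on.
#' @param report A `"cfa_outliers"` from [mahalanobis_outliers()].
#' @param method Estimation method for the refit.
#' @param population Population loading vector for the congruence score;
#'   defaults to the generating model stored in a `"cfa_sample"`.
#' @return List with `fit` (`"cfa_fit"`), `congruence`
#'   (`"cfa_congruence"` or NULL if no population vector is available),
#'   `n_before`, `n_after`.
#' @export
refit_after_removal <- function(x, report, method = "ML",
                                population = NULL) {
  stopifnot(inherits(report, "cfa_outliers"))
  if (is.null(population)) {
    model <- attr(x, "model")
    if (!is.null(model)) population <- model$loadings
  }
  xm <- as.matrix(unclass(x))
  attr(xm, "model") <- NULL
  if (nrow(xm) != report$n)
    stop("'report' was computed from a different number of cases")
  keep <- setdiff(seq_len(nrow(xm)), report$flagged)
  if (length(keep) <= ncol(xm) + 1)
    stop("degenerate: removal leaves too few cases to refit")
  xr <- xm[keep, , drop = FALSE]
  moments <- compute_moments(xr)
  fit <- fit_cfa(moments, method = method)
  ck <- NULL
  if (!is.null(population))
    ck <- congruence(standardized_loadings(fit, moments), population)
  list(fit = fit, congruence = ck, n_before = report$n,
       n_after = length(keep))
}
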