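#' Define a one-factor population measurement model
#'
#' Builds the population common factor model \eqn{\Sigma = \Lambda \Phi
#' \Lambda' + \Theta} for a single latent factor with unit variance. Under the
#' equal-loading, unit-variance design used throughout the simulation study,
#' the unique variances default to \eqn{1 - \lambda_i^2} so every indicator
#' has population variance one and the implied matrix is a correlation
#' matrix.
#'
#' @param loadings Numeric vector of population factor loadings
#'   \eqn{\lambda_i}, one per indicator, each in (-1, 1) when
#'   `unique_variances` is left at its default.
#' @param factor_variance Positive scalar \eqn{\Phi}; fixed at 1 for
#'   identification (the study design).
#' @param unique_variances Optional nonnegative vector \eqn{\theta_i}
#'   (diagonal of \eqn{\Theta}). Defaults to `1 - loadings^2`.
#' @return An object of class `"cfa_model"`: a list with elements
#'   `loadings`, `factor_variance`, `unique_variances`, `p` and `n_factors`.
#' @seealso [implied_sigma()], [generate_sample()]
#' @examples
#' m <- one_factor_model(rep(0.4, 4))
#' implied_sigma(m)
#' @export
one_factor_model <- function(loadings, factor_variance = 1,
                             unique_variances = NULL) {
  loadings <- as.numeric(loadings)
  p <- length(loadings)
  if (p < 1L || anyNA(loadings))
    stop("'loadings' must be a non-empty numeric vector without NAs")
  if (!is.numeric(factor_variance) || length(factor_variance) != 1L ||
      factor_variance <= 0)
    stop("'factor_variance' must be a positive scalar")
  if (is.null(unique_variances)) {
    if (any(abs(loadings) >= 1))
      stop("default unique variances 1 - lambda^2 require |loadings| < 1")
    unique_variances <- 1 - loadings^2
  }
  unique_variances <- as.numeric(unique_variances)
  if (length(unique_variances) != p)
    stop("'unique_variances' must have one entry per loading")
  if (any(unique_variances < 0))
    stop("'unique_variances' must be nonnegative")
  structure(
    list(loadings = loadings, factor_variance = factor_variance,
         unique_variances = unique_variances, p = p, n_factors = 1L),
    class = "cfa_model")
}

#' Model-implied population covariance matrix
#'
#' Computes \eqn{\Sigma = \Lambda \Phi \Lambda' + \Theta}. With the default
#' equal-loading, unit-variance design this is a correlation matrix: unit
#' diagonal and all off-diagonal entries \eqn{\lambda^2 \Phi}.
#'
#' @param model A `"cfa_model"` object from [one_factor_model()].
#' @return A symmetric `p x p` matrix.
#' @export
implied_sigma <- function(model) {
  if (!inherits(model, "cfa_model"))
    stop("'model' must be a \"cfa_model\" object")
  lam <- model$loadings
  sigma <- tcrossprod(lam) * model$factor_variance
  diag(sigma) <- diag(sigma) + model$unique_variances
  dimnames(sigma) <- list(indicator_names(model$p), indicator_names(model$p))
  sigma
}

indicator_names <- function(p) paste0("X", seq_len(p))

#' @export
print.cfa_model <- function(x, ...) {
  cat("One-factor population model (", x$p, " indicators)\n", sep = "")
  cat("  loadings:        ", paste(format(x$loadings, digits = 3),
                                   collapse = " "), "\n")
  cat("  factor variance: ", format(x$factor_variance), "\n")
  cat("  unique variances:", paste(format(x$unique_variances, digits = 3),
                                   collapse = " "), "\n")
  invisible(x)
}
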