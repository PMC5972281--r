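# One-factor CFA estimation by iterative minimization of a discrepancy
# function between the model-implied matrix Sigma* = lambda lambda' +
# diag(theta) (factor variance fixed at 1) and the observed moment matrix.
#
# ML uses the normal-theory log-likelihood discrepancy on the covariance
# matrix S:
#   F_ML = log|Sigma*| + tr(S Sigma*^-1) - log|S| - p
# ULS uses the sum of squared non-redundant residuals on the correlation
# matrix R, excluding the fixed unit diagonal, with theta = 1 - lambda^2
# implied by the unit diagonal:
#   F_ULS = sum_{i<j} (lambda_i lambda_j - r_ij)^2
#
# Unique variances are left unconstrained during ML optimization so that
# Heywood cases (negative theta estimates) can occur and be detected, as in
# the LISREL runs the study emulates.

.ml_objective <- function(par, S, p, logdetS) {
  lam <- par[seq_len(p)]
  sigma <- tcrossprod(lam)
  diag(sigma) <- diag(sigma) + par[p + seq_len(p)]
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)  # outside the PD cone; forces backtracking
  sinv <- chol2inv(ch)
  2 * sum(log(diag(ch))) + sum(sinv * S) - logdetS - p
}

.ml_gradient <- function(par, S, p, logdetS) {
  lam <- par[seq_len(p)]
  sigma <- tcrossprod(lam)
  diag(sigma) <- diag(sigma) + par[p + seq_len(p)]
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(numeric(2 * p))
  sinv <- chol2inv(ch)
  a <- sinv - sinv %*% S %*% sinv  # dF = tr(A dSigma)
  c(2 * drop(a %*% lam), diag(a))
}

.uls_objective <- function(lam, R) {
  e <- tcrossprod(lam) - R
  diag(e) <- 0
  sum(e^2) / 2
}

.uls_gradient <- function(lam, R) {
  e <- tcrossprod(lam) - R
  diag(e) <- 0
  2 * drop(e %*% lam)
}

.start_values <- function(M) {
  # first principal axis of the input matrix, scaled to its eigenvalue
  e <- eigen(M, symmetric = TRUE)
  lam0 <- e$vectors[, 1] * sqrt(max(e$values[1], .Machine$double.eps))
  if (sum(lam0) < 0) lam0 <- -lam0
  th0 <- pmax(diag(M) - lam0^2, 0.05 * diag(M))
  list(lam = lam0, theta = th0)
}

# Minimize with restarts until the gradient norm tolerance is met or the
# iteration cap is exhausted (the study fixes the cap at 250, read as the
# LISREL IT keyword).
.minimize <- function(par, fn, gr, max_iter, tol) {
  used <- 0L
  repeat {
    opt <- stats::nlminb(start = par, objective = fn, gradient = gr,
                         control = list(iter.max = max_iter - used,
                                        eval.max = 4L * max_iter,
                                        rel.tol = 1e-12, x.tol = 1e-12))
    used <- used + opt$iterations
    g <- gr(opt$par)
    gnorm <- sqrt(sum(g^2))
    if (gnorm < tol || used >= max_iter ||
        max(abs(opt$par - par)) < 1e-14) break
    par <- opt$par
  }
  par <- opt$par
  f <- opt$objective
  # Newton polish: nlminb can stall on its relative criteria with the
  # gradient still marginally above tolerance near a well-behaved optimum.
  while (is.finite(gnorm) && gnorm >= tol && used < max_iter) {
    H <- tryCatch(stats::optimHess(par, fn, gr), error = function(e) NULL)
    step <- if (is.null(H)) NULL else
      tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    ok <- FALSE
    for (damp in c(1, 0.5, 0.25, 0.1)) {
      cand <- par + damp * step
      fc <- fn(cand)
      if (is.finite(fc) && fc <= f + 1e-12) {
        gc <- gr(cand)
        gn <- sqrt(sum(gc^2))
        if (is.finite(gn) && gn < gnorm) {
          par <- cand; f <- fc; g <- gc; gnorm <- gn; ok <- TRUE
          break
        }
      }
    }
    used <- used + 1L
    if (!ok) break
  }
  list(par = par, objective = f, iterations = used,
       converged = is.finite(gnorm) && gnorm < tol)
}

#' Fit the one-factor CFA model to sample moments
#'
#' Estimates loadings and unique variances of the one-factor model with the
#' factor variance fixed at 1, by iterative minimization of the ML
#' discrepancy on the covariance matrix `S` or the ULS discrepancy on the
#' correlation matrix `R` (the input convention the study follows).
#' Convergence means the gradient norm fell below `tol` within `max_iter`
#' iterations; fits that exhaust the cap are returned with
#' `converged = FALSE` and status `"nonconvergent"`, never as an error.
#' Negative unique-variance estimates are returned as-is and flagged as
#' Heywood cases via [classify_solution()].
#'
#' @param moments A `"cfa_moments"` object ([compute_moments()],
#'   [as_moments()]).
#' @param method `"ML"` (fits `S`) or `"ULS"` (fits `R`).
#' @param max_iter Iteration cap (study default 250).
#' @param tol Gradient-norm convergence tolerance.
#' @param se For ML: compute standard errors of the unstandardized loadings
#'   from the inverse observed information (see [loading_standard_errors()]).
#' @return A `"cfa_fit"` list: `loadings`, `unique_variances`,
#'   `standard_errors` (NA when unavailable), `method`, `input_matrix`,
#'   `converged`, `n_iterations`, `f_min`, `status`, `df`, `n`, `p`.
#'   The loading vector sign is resolved so that its sum is nonnegative.
#' @export
fit_cfa <- function(moments, method = c("ML", "ULS"), max_iter = 250L,
                    tol = 1e-6, se = TRUE) {
  method <- match.arg(method)
  if (!inherits(moments, "cfa_moments"))
    stop("'moments' must be a \"cfa_moments\" object")
  p <- moments$p
  df <- p * (p + 1L) / 2L - 2L * p

  if (method == "ML") {
    S <- moments$S
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch))
      stop("estimation-input error: S is not positive definite; ",
           "see is_positive_definite() and mahalanobis_outliers()")
    logdetS <- 2 * sum(log(diag(ch)))
    st <- .start_values(S)
    opt <- .minimize(c(st$lam, st$theta),
                     function(par) .ml_objective(par, S, p, logdetS),
                     function(par) .ml_gradient(par, S, p, logdetS),
                     max_iter = max_iter, tol = tol)
    lam <- opt$par[seq_len(p)]
    theta <- opt$par[p + seq_len(p)]
    input <- "S"
  } else {
    R <- moments$R
    st <- .start_values(R)
    opt <- .minimize(st$lam,
                     function(par) .uls_objective(par, R),
                     function(par) .uls_gradient(par, R),
                     max_iter = max_iter, tol = tol)
    lam <- opt$par
    theta <- 1 - lam^2  # unit diagonal of R is fixed, not fitted
    input <- "R"
  }
  if (sum(lam) < 0) lam <- -lam
  lam <- unname(lam); theta <- unname(theta)

  fit <- structure(
    list(loadings = lam, unique_variances = theta,
         standard_errors = rep(NA_real_, p), method = method,
         input_matrix = input, converged = opt$converged,
         n_iterations = opt$iterations, f_min = opt$objective,
         df = df, n = moments$n, p = p, status = NA_character_),
    class = "cfa_fit")
  fit$status <- classify_solution(fit)
  if (se && method == "ML" && fit$status == "proper")
    fit$standard_errors <- loading_standard_errors(fit, moments)
  fit
}

#' Classify a fit as proper, nonconvergent or Heywood
#'
#' A solution is `"nonconvergent"` if the optimizer did not meet the
#' gradient tolerance within the iteration cap; otherwise `"heywood"` if
#' any unique-variance estimate is strictly negative (for ULS on `R`,
#' equivalently a standardized loading beyond 1); otherwise `"proper"`.
#' A boundary estimate of exactly zero counts as proper.
#'
#' @param fit A `"cfa_fit"`.
#' @return One of `"proper"`, `"nonconvergent"`, `"heywood"`.
#' @export
classify_solution <- function(fit) {
  stopifnot(inherits(fit, "cfa_fit"))
  if (!isTRUE(fit$converged)) return("nonconvergent")
  if (min(fit$unique_variances) < 0) return("heywood")
  "proper"
}

#' Standardized loadings
#'
#' Converts unstandardized ML loadings to the standardized metric,
#' \eqn{\lambda_i \sqrt{\Phi} / \sqrt{s_{ii}}}. With the factor variance
#' fixed at 1 this divides each loading by the observed standard deviation
#' of its indicator; for unit-variance input (or a ULS fit to `R`) the
#' standardized and unstandardized loadings coincide.
#'
#' @param fit A `"cfa_fit"`.
#' @param moments The `"cfa_moments"` the model was fitted to.
#' @return Numeric vector of standardized loadings.
#' @export
standardized_loadings <- function(fit, moments) {
  stopifnot(inherits(fit, "cfa_fit"), inherits(moments, "cfa_moments"))
  s <- diag(if (fit$input_matrix == "S") moments$S else moments$R)
  if (any(s <= 0)) stop("degenerate input: nonpositive observed variance")
  unname(fit$loadings / sqrt(s))
}

#' Standard errors of unstandardized ML loadings
#'
#' Asymptotic standard errors from the inverse of the observed information
#' of the ML discrepancy: the covariance matrix of the estimates is
#' \eqn{2/(n-1)} times the inverse Hessian of `F_ML` at the optimum,
#' reported in the unit of measurement of the indicators.
#'
#' @param fit A converged, proper ML `"cfa_fit"`.
#' @param moments The fitted `"cfa_moments"`.
#' @return Numeric vector of loading standard errors, or all-NA (with a
#'   warning suppressed into the NA flag) when the information matrix is
#'   singular.
#' @export
loading_standard_errors <- function(fit, moments) {
  stopifnot(inherits(fit, "cfa_fit"))
  if (fit$method != "ML")
    stop("standard errors are provided for ML fits only")
  p <- fit$p
  S <- moments$S
  logdetS <- determinant(S)$modulus[1]
  par <- c(fit$loadings, fit$unique_variances)
  H <- tryCatch(
    stats::optimHess(par,
                     function(x) .ml_objective(x, S, p, logdetS),
                     function(x) .ml_gradient(x, S, p, logdetS)),
    error = function(e) NULL)
  if (is.null(H)) return(rep(NA_real_, p))
  acov <- tryCatch(solve(H) * 2 / (fit$n - 1), error = function(e) NULL)
  if (is.null(acov)) return(rep(NA_real_, p))
  v <- diag(acov)[seq_len(p)]
  ifelse(v > 0, sqrt(v), NA_real_)
}

#' t statistics for the unstandardized loadings
#'
#' @param fit A `"cfa_fit"` with standard errors available.
#' @return Vector `loadings / standard_errors`; NA where the SE is
#'   unavailable.
#' @export
loading_t_values <- function(fit) {
  stopifnot(inherits(fit, "cfa_fit"))
  fit$loadings / fit$standard_errors
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("One-factor CFA fit (%s on %s), n = %d, p = %d\n",
              x$method, x$input_matrix, x$n, x$p))
  cat(sprintf("  status: %s (%d iterations, F = %.6g, df = %d)\n",
              x$status, x$n_iterations, x$f_min, x$df))
  cat("  loadings:        ", paste(format(round(x$loadings, 3)),
                                   collapse = " "), "\n")
  cat("  unique variances:", paste(format(round(x$unique_variances, 3)),
                                   collapse = " "), "\n")
  if (any(is.finite(x$standard_errors)))
    cat("  SE(loadings):    ", paste(format(round(x$standard_errors, 3)),
                                     collapse = " "), "\n")
  invisible(x)
}
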