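# Overall goodness-of-fit: the chi-square test of exact fit and the two
# derived indices the study tracks, RMSEA (Steiger-Lind) and CFI (relative
# noncentrality against the independence baseline, clipped to [0, 1]).

#' Chi-square test of exact fit
#'
#' Transforms the minimized discrepancy into the test statistic
#' \eqn{\chi^2 = (n - 1) F_{min}} with its upper-tail p-value. The `n - 1`
#' multiplier is the LISREL convention for covariance-matrix input. For ULS
#' fits the same transformation is applied but the statistic is not
#' comparable to the ML chi-square (flagged by [fit_indices()]).
#'
#' @param f_min Minimized discrepancy function value (nonnegative).
#' @param n Sample size.
#' @param df Model degrees of freedom; must be at least 1.
#' @return List with `chi_square` and `p_value`.
#' @export
chi_square_test <- function(f_min, n, df) {
  if (df <= 0) stop("saturated model: df must be >= 1 for the fit test")
  if (f_min < 0) stop("'f_min' must be nonnegative")
  chi <- (n - 1) * f_min
  list(chi_square = chi,
       p_value = stats::pchisq(chi, df, lower.tail = FALSE))
}

#' Root mean square error of approximation
#'
#' \eqn{\sqrt{\max(\chi^2 - df, 0) / (df (n - 1))}}; zero whenever the
#' statistic does not exceed its degrees of freedom.
#'
#' @param chi_square Chi-square statistic.
#' @param df Model degrees of freedom (>= 1).
#' @param n Sample size (>= 2).
#' @return RMSEA value.
#' @export
rmsea <- function(chi_square, df, n) {
  stopifnot(df >= 1, n >= 2)
  sqrt(max(chi_square - df, 0) / (df * (n - 1)))
}

#' Comparative fit index
#'
#' Improvement of the fitted model over the independence baseline on the
#' noncentrality scale: the raw relative-noncentrality ratio
#' \eqn{1 - (\chi^2 - df) / (\chi^2_B - df_B)}, clipped to `[0, 1]`. This
#' matches the index as printed by LISREL for these models: when both the
#' model and the baseline statistic fall below their degrees of freedom the
#' clipped raw ratio is reported (often 0 for weakly correlated data),
#' rather than forcing the index to 1.
#'
#' @param chi_square,df Model test statistic and degrees of freedom.
#' @param baseline_chi_square,baseline_df Independence-model statistic and
#'   degrees of freedom from [independence_model()].
#' @return CFI in `[0, 1]`.
#' @export
cfi <- function(chi_square, df, baseline_chi_square, baseline_df) {
  t_m <- chi_square - df
  t_b <- baseline_chi_square - baseline_df
  if (t_b == 0) return(if (t_m <= 0) 1 else 0)
  min(max(1 - t_m / t_b, 0), 1)
}

#' Independence (zero-covariance) baseline model
#'
#' Fits the baseline with all covariances zero and variances free, the
#' reference model of the CFI. For ML the diagonal model reproduces the
#' variances exactly, so the baseline statistic reduces to
#' \eqn{-(n-1) \log |R|} with \eqn{df = p(p-1)/2}. For ULS the baseline
#' discrepancy is the sum of squared off-diagonal correlations, transformed
#' with the same `n - 1` multiplier.
#'
#' @param moments A `"cfa_moments"`.
#' @param method `"ML"` or `"ULS"`.
#' @return List with `baseline_chi_square` and `baseline_df`.
#' @export
independence_model <- function(moments, method = c("ML", "ULS")) {
  method <- match.arg(method)
  stopifnot(inherits(moments, "cfa_moments"))
  p <- moments$p
  if (method == "ML") {
    ld <- determinant(moments$R)
    if (!is.finite(ld$modulus) || ld$sign <= 0)
      stop("estimation-input error: singular correlation matrix")
    chi <- -(moments$n - 1) * ld$modulus[1]
  } else {
    chi <- (moments$n - 1) * sum(moments$R[upper.tri(moments$R)]^2)
  }
  list(baseline_chi_square = as.numeric(chi),
       baseline_df = p * (p - 1L) / 2L)
}

#' All overall-fit measures for a fitted model
#'
#' Convenience wrapper computing the chi-square test, RMSEA and CFI (with
#' its independence baseline) for a `"cfa_fit"`.
#'
#' @param fit A `"cfa_fit"`.
#' @param moments The `"cfa_moments"` the model was fitted to.
#' @return A `"cfa_fit_indices"` list: `chi_square`, `df`, `p_value`,
#'   `rmsea`, `cfi`, `baseline_chi_square`, `baseline_df`,
#'   `ml_comparable` (FALSE for ULS: its rescaled statistic is not on the
#'   ML chi-square scale).
#' @export
fit_indices <- function(fit, moments) {
  stopifnot(inherits(fit, "cfa_fit"), inherits(moments, "cfa_moments"))
  ct <- chi_square_test(fit$f_min, fit$n, fit$df)
  base <- independence_model(moments, fit$method)
  structure(
    list(chi_square = ct$chi_square, df = fit$df, p_value = ct$p_value,
         rmsea = rmsea(ct$chi_square, fit$df, fit$n),
         cfi = cfi(ct$chi_square, fit$df, base$baseline_chi_square,
                   base$baseline_df),
         baseline_chi_square = base$baseline_chi_square,
         baseline_df = base$baseline_df,
         ml_comparable = fit$method == "ML"),
    class = "cfa_fit_indices")
}

#' @export
print.cfa_fit_indices <- function(x, ...) {
  cat(sprintf("chi-square = %.3f, df = %d, p = %.4f\n",
              x$chi_square, x$df, x$p_value))
  cat(sprintf("RMSEA = %.4f, CFI = %.4f (baseline chi-square = %.2f, df = %d)\n",
              x$rmsea, x$cfi, x$baseline_chi_square, x$baseline_df))
  if (!x$ml_comparable)
    cat("note: ULS statistic, not comparable to the ML chi-square scale\n")
  invisible(x)
}
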