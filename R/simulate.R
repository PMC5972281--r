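#' Simulation condition of the study grid
#'
#' One cell of the simulation design: a loading magnitude, a number of
#' indicators per factor, a sample size and a replication count. The full
#' study design is the 3 x 5 x 4 grid of `lambda` in {0.2, 0.3, 0.4},
#' `p` in {4, 5, 6, 7, 15} and `N` in {200, 300, 400, 500} with 1,000
#' replications per condition.
#'
#' @param lambda Population loading magnitude shared by all indicators.
#' @param p Number of indicators per factor.
#' @param N Sample size of each replication.
#' @param n_replications Number of Monte Carlo replications.
#' @return A `"cfa_condition"` list.
#' @export
sim_condition <- function(lambda, p, N, n_replications = 1000L) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda > -1, lambda < 1,
            p >= 2, N >= p + 1, n_replications >= 1)
  structure(list(lambda = lambda, p = as.integer(p), N = as.integer(N),
                 n_replications = as.integer(n_replications)),
            class = "cfa_condition")
}

#' Full factorial study grid
#'
#' @param lambda,p,N Vectors of condition levels; defaults are the study
#'   design levels.
#' @param n_replications Replications per condition (default 1000).
#' @return A data frame with one row per condition (`lambda`, `p`, `N`,
#'   `n_replications`), ordered lambda-major.
#' @export
study_grid <- function(lambda = c(0.2, 0.3, 0.4), p = c(4, 5, 6, 7, 15),
                       N = c(200, 300, 400, 500), n_replications = 1000L) {
  g <- expand.grid(N = as.integer(N), p = as.integer(p), lambda = lambda,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("lambda", "p", "N")]
  g$n_replications <- as.integer(n_replications)
  g[order(g$lambda, g$p, g$N), , drop = FALSE]
}

#' Deterministic per-replication seed
#'
#' Derives a 32-bit seed for one replication of one condition from the
#' study master seed, so any single replication (its `CASE`) can be
#' regenerated in isolation without rerunning the study.
#'
#' @param master_seed Integer master seed of the study.
#' @param lambda,p,N Condition labels.
#' @param case 1-based replication index within the condition.
#' @return An integer in [0, 2^31 - 2] suitable for [set.seed()].
#' @export
replication_seed <- function(master_seed, lambda, p, N, case) {
  m <- 2147483647  # 2^31 - 1, keeps every intermediate below 2^53
  h <- (as.double(master_seed) %% m) * 1000003 +
    round(100 * lambda) * 10007 + as.double(p) * 101 + as.double(N)
  h <- (h %% m) * 1000003 + as.double(case)
  as.integer(h %% m)
}

#' Generate one replication sample from the population model
#'
#' Draws an `n x p` data matrix according to the common factor model
#' \eqn{x = \Lambda \xi + \delta}: a standard normal factor score per case
#' and independent normal unique parts with variances \eqn{\theta_i}.
#'
#' @param model A `"cfa_model"` object.
#' @param n Sample size; must exceed the number of indicators.
#' @param seed Optional integer seed set before drawing, making the sample
#'   reproducible in isolation (see [replication_seed()]).
#' @param case Optional replication identifier stored with the sample.
#' @return A `"cfa_sample"`: the numeric matrix with attributes `model`,
#'   `case` and `seed`.
#' @export
generate_sample <- function(model, n, seed = NULL, case = NA_integer_) {
  if (!inherits(model, "cfa_model"))
    stop("'model' must be a \"cfa_model\" object")
  p <- model$p
  if (n <= p)
    stop("degenerate sample: n must exceed the number of indicators")
  if (!is.null(seed)) set.seed(as.integer(seed))
  xi <- rnorm(n) * sqrt(model$factor_variance)
  delta <- matrix(rnorm(n * p), n, p) *
    rep(sqrt(model$unique_variances), each = n)
  x <- tcrossprod(xi, model$loadings) + delta
  colnames(x) <- indicator_names(p)
  structure(x, model = model, case = case, seed = seed, class = "cfa_sample")
}

#' Sample moment matrices
#'
#' Computes the sample covariance matrix `S` (denominator `n - 1`) and the
#' correlation matrix `R` derived from it. `S` is the input for ML
#' estimation, `R` for ULS.
#'
#' @param x A data matrix or `"cfa_sample"`.
#' @return A `"cfa_moments"` list with elements `S`, `R`, `n` and `p`.
#' @export
compute_moments <- function(x) {
  x <- unclass(x)
  attr(x, "model") <- NULL
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stop("need more rows than columns to compute moments")
  S <- stats::cov(x)
  if (any(diag(S) <= 0))
    stop("degenerate data: zero-variance column")
  structure(list(S = S, R = stats::cov2cor(S), n = n, p = p),
            class = "cfa_moments")
}

#' Wrap externally supplied moment matrices
#'
#' Accepts a covariance or correlation matrix computed elsewhere (for
#' example read from a whitespace-delimited text file) so that it can be
#' passed to [fit_cfa()].
#'
#' @param S Symmetric covariance matrix.
#' @param n Sample size the matrix was computed from.
#' @return A `"cfa_moments"` list, as [compute_moments()].
#' @export
as_moments <- function(S, n) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8)
    stop("'S' must be a symmetric square matrix")
  S <- (S + t(S)) / 2
  if (any(diag(S) <= 0)) stop("'S' must have positive diagonal")
  structure(list(S = S, R = stats::cov2cor(S), n = as.integer(n),
                 p = ncol(S)), class = "cfa_moments")
}

#' Recode continuous indicators into ordered categories
#'
#' Maps each value to the number of thresholds it exceeds, producing
#' integer categories `0 ... length(thresholds)`.
#'
#' @param x Data matrix or `"cfa_sample"`.
#' @param thresholds Strictly ascending numeric vector of cut points.
#' @return An integer matrix of the same dimension.
#' @export
discretize <- function(x, thresholds) {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) && any(diff(thresholds) <= 0))
    stop("'thresholds' must be strictly ascending")
  xm <- as.matrix(unclass(x))
  out <- matrix(0L, nrow(xm), ncol(xm), dimnames = dimnames(xm))
  for (t in thresholds) out <- out + (xm > t)
  storage.mode(out) <- "integer"
  out
}

#' Write replication raw data for a condition as CSV
#'
#' One file per condition, named `N{N}L{100*lambda}` after the convention of
#' the study's deposited data (e.g. `N200L020_p4.csv`), with a `CASE`
#' column identifying the replication each row belongs to.
#'
#' @param condition A `"cfa_condition"`.
#' @param dir Output directory.
#' @param master_seed Study master seed (drives [replication_seed()]).
#' @return The file path, invisibly.
#' @export
write_condition_data <- function(condition, dir, master_seed = 1L) {
  stopifnot(inherits(condition, "cfa_condition"))
  model <- one_factor_model(rep(condition$lambda, condition$p))
  path <- file.path(dir, sprintf("N%dL%03d_p%d.csv", condition$N,
                                 round(100 * condition$lambda), condition$p))
  rows <- vector("list", condition$n_replications)
  for (r in seq_len(condition$n_replications)) {
    s <- generate_sample(model, condition$N,
                         seed = replication_seed(master_seed,
                                                 condition$lambda,
                                                 condition$p, condition$N, r),
                         case = r)
    rows[[r]] <- data.frame(CASE = r, unclass(s))
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
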