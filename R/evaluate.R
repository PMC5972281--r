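# Parameter-recovery scoring: Tucker's coefficient of congruence between
# estimated and population loading vectors, pooled summary cells, and the
# congruence-ranking versus chi-square p-value analysis.

#' Coefficient of congruence between loading vectors
#'
#' Tucker's congruence
#' \eqn{C_k = \sum \lambda^*_i \lambda_i / \sqrt{\sum \lambda^{*2}_i
#' \sum \lambda^2_i}}, the cosine similarity between the estimated and
#' population loading vectors. Scale-invariant in each argument and
#' invariant to a simultaneous sign flip of both vectors. Interpretation
#' follows the 0.85/0.95 cutoffs: `"fair"` in [0.85, 0.95], `"good"` above
#' 0.95, `"poor"` below.
#'
#' @param estimated,population Numeric loading vectors of equal length
#'   (>= 2); the population vector must be nonzero.
#' @return A `"cfa_congruence"` list with `value` and `interpretation`
#'   (`NA` flagged when the estimated vector is all zero).
#' @export
congruence <- function(estimated, population) {
  estimated <- as.numeric(estimated); population <- as.numeric(population)
  if (length(estimated) != length(population) || length(estimated) < 2)
    stop("loading vectors must have equal length >= 2")
  if (all(population == 0)) stop("population loading vector must be nonzero")
  value <- .congruence(estimated, population)
  structure(list(value = value,
                 interpretation = congruence_interpretation(value)),
            class = "cfa_congruence")
}

.congruence <- function(estimated, population) {
  se <- sum(estimated^2)
  if (se == 0) return(NA_real_)
  sum(estimated * population) / sqrt(se * sum(population^2))
}

congruence_interpretation <- function(value) {
  if (is.na(value)) return(NA_character_)
  if (value > 0.95) "good" else if (value >= 0.85) "fair" else "poor"
}

#' @export
print.cfa_congruence <- function(x, ...) {
  cat(sprintf("coefficient of congruence C_k = %.4f (%s similarity)\n",
              x$value, x$interpretation))
  invisible(x)
}

.p_group <- function(p) ifelse(p <= 6, "4-6", ifelse(p == 7, "7", "15"))
.N_group <- function(N) ifelse(N <= 300, "200-300", "400-500")

#' Pooled summary cells of a study results table
#'
#' Aggregates per-replication results into the pooled cell layout of the
#' study's summary table: loading magnitude by indicator group (4-6, 7, 15)
#' by sample-size group (200-300, 400-500). The proper-solution rate is
#' over all replications of the cell; all other statistics are over proper
#' solutions only. The per-replication "average loading" is the mean of the
#' standardized loading estimates, with the cell min-max taken over these
#' replication averages.
#'
#' @param results Per-replication data frame from [run_study()].
#' @param method Which estimation method's rows to summarize.
#' @return A `"cfa_summary"` data frame, one row per cell: counts,
#'   `proper_rate` (percent), mean/SD/min/max of the average loading, and
#'   mean/SD of congruence, RMSEA and CFI. Cells without proper solutions
#'   carry NA statistics; single-fit cells carry NA SDs.
#' @export
summarize_study <- function(results, method = "ML") {
  stopifnot(is.data.frame(results))
  d <- results[results$method == method, , drop = FALSE]
  if (!nrow(d)) stop("no rows for method ", method)
  d$p_group <- factor(.p_group(d$p), levels = c("4-6", "7", "15"))
  d$N_group <- factor(.N_group(d$N), levels = c("200-300", "400-500"))
  d$lambda_f <- factor(d$lambda)
  cells <- split(d, list(d$lambda_f, d$p_group, d$N_group), drop = FALSE)
  rows <- lapply(cells, function(cell) {
    if (!nrow(cell)) return(NULL)
    proper <- cell[cell$status == "proper", , drop = FALSE]
    stat <- function(x, f) if (nrow(proper)) f(x, na.rm = TRUE) else NA_real_
    sdx <- function(x) if (nrow(proper) > 1) stats::sd(x, na.rm = TRUE) else NA_real_
    data.frame(
      lambda = cell$lambda[1],
      p_group = as.character(cell$p_group[1]),
      N_group = as.character(cell$N_group[1]),
      n_fits = nrow(cell), n_proper = nrow(proper),
      proper_rate = 100 * nrow(proper) / nrow(cell),
      mean_avg_loading = stat(proper$avg_loading, mean),
      sd_avg_loading = sdx(proper$avg_loading),
      min_avg_loading = stat(proper$avg_loading, min),
      max_avg_loading = stat(proper$avg_loading, max),
      mean_ck = stat(proper$ck, mean), sd_ck = sdx(proper$ck),
      mean_rmsea = stat(proper$rmsea, mean), sd_rmsea = sdx(proper$rmsea),
      mean_cfi = stat(proper$cfi, mean), sd_cfi = sdx(proper$cfi))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$lambda, factor(out$p_group, c("4-6", "7", "15")),
                   out$N_group), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cfa_summary", "data.frame")
  out
}

#' @export
print.cfa_summary <- function(x, digits = 2, ...) {
  cat("Pooled summary of estimated CFA solutions (proper solutions only)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Congruence ranking against the chi-square p-value
#'
#' Ranks proper solutions from highest congruence (rank 1) to lowest
#' (last), pairs each rank with its chi-square p-value, and reports the
#' Spearman rank correlation between congruence and p-value; a correlation
#' near zero reproduces the finding that overall fit carries no information
#' about parameter-recovery quality. Ties share mean ranks.
#'
#' @param results Per-replication data frame from [run_study()].
#' @param method Estimation method to analyze.
#' @return A `"cfa_ranking"` data frame (`ck_rank`, `ck`, `p_value`) with
#'   attributes `spearman_rho` and `n`.
#' @export
rank_congruence_vs_p <- function(results, method = "ML") {
  d <- results[results$method == method & results$status == "proper", ,
               drop = FALSE]
  d <- d[is.finite(d$ck) & is.finite(d$p_value), , drop = FALSE]
  if (!nrow(d)) stop("no proper solutions to rank")
  out <- data.frame(ck_rank = rank(-d$ck, ties.method = "average"),
                    ck = d$ck, p_value = d$p_value)
  out <- out[order(out$ck_rank), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "spearman_rho") <- stats::cor(d$ck, d$p_value,
                                          method = "spearman")
  attr(out, "n") <- nrow(d)
  class(out) <- c("cfa_ranking", "data.frame")
  out
}

#' @export
print.cfa_ranking <- function(x, ...) {
  cat(sprintf("congruence ranking of %d proper solutions; Spearman rho(C_k, p) = %.4f\n",
              attr(x, "n"), attr(x, "spearman_rho")))
  print(utils::head(as.data.frame(x)), row.names = FALSE)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Scatter plot of congruence rank versus chi-square p-value
#'
#' @param x A `"cfa_ranking"` object.
#' @param ... Passed to [plot()].
#' @export
plot.cfa_ranking <- function(x, ...) {
  plot(x$ck_rank, x$p_value, pch = 16, cex = 0.4,
       xlab = "ranking of coefficient of congruence (1 = highest C_k)",
       ylab = expression(chi^2 ~ "p-value"), ...)
  invisible(x)
}
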