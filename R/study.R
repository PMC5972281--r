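# Study driver: runs the full condition grid, one fit per replication and
# method, with per-replication seed substreams so any CASE can be
# regenerated in isolation.

#' Configuration of a simulation study
#'
#' @param lambda,p,N Condition levels; defaults are the full 3 x 5 x 4
#'   study grid.
#' @param n_replications Replications per condition (study default 1000).
#' @param methods Estimation methods to run, subset of `c("ML", "ULS")`.
#'   ML is fitted to the sample covariance matrix, ULS to the correlation
#'   matrix.
#' @param master_seed Integer master seed; every replication's seed is
#'   derived from it deterministically (see [replication_seed()]).
#' @param compute_se Compute ML loading standard errors per proper fit.
#' @param keep_loadings Keep per-indicator loading (and SE) columns in the
#'   results table, NA-padded to the largest `p` of the grid.
#' @param output_dir Optional directory; when set, [run_study()] writes the
#'   per-method results CSV and the pooled summary CSV there.
#' @param verbose Log per-condition progress and improper-solution counts.
#' @return A `"cfa_study_config"` list with a `grid` data frame.
#' @export
study_config <- function(lambda = c(0.2, 0.3, 0.4), p = c(4, 5, 6, 7, 15),
                         N = c(200, 300, 400, 500), n_replications = 1000L,
                         methods = "ML", master_seed = 1L,
                         compute_se = TRUE, keep_loadings = FALSE,
                         output_dir = NULL, verbose = FALSE) {
  methods <- match.arg(methods, c("ML", "ULS"), several.ok = TRUE)
  grid <- study_grid(lambda = lambda, p = p, N = N,
                     n_replications = n_replications)
  structure(list(grid = grid, methods = methods,
                 master_seed = as.integer(master_seed),
                 compute_se = isTRUE(compute_se),
                 keep_loadings = isTRUE(keep_loadings),
                 output_dir = output_dir, verbose = isTRUE(verbose)),
            class = "cfa_study_config")
}

#' Read a study configuration from a YAML file
#'
#' Accepts the fields of [study_config()] (`lambda`, `p`, `N`,
#' `n_replications`, `methods`, `master_seed`, ...) as top-level YAML keys;
#' missing fields take the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `"cfa_study_config"`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `N:` key as the boolean FALSE; map it back
  names(cfg)[names(cfg) == "FALSE"] <- "N"
  known <- names(formals(study_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(study_config, cfg)
}

#' Run the Monte Carlo study
#'
#' For every condition and replication: generate the sample, compute the
#' moment matrices, fit the one-factor model by each configured method,
#' classify the solution, compute fit indices and score congruence against
#' the population loadings. Replication-level failures are recorded in the
#' `status` column (`"error"`) and never abort the study. The whole run is
#' reproducible from the master seed, and any single replication can be
#' regenerated with [locate_case()].
#'
#' @param config A `"cfa_study_config"`.
#' @return A data frame with one row per condition x replication x method:
#'   condition labels, `CASE`, `seed`, `status`, `converged`,
#'   `n_iterations`, `f_min`, `chi_square`, `df`, `p_value`, `rmsea`,
#'   `cfi`, `avg_loading` (mean standardized loading), `ck`
#'   (congruence with the population vector), `mean_se`, and, when
#'   `keep_loadings` is set, `loading1..` / `se1..` columns.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "cfa_study_config"))
  grid <- config$grid
  max_p <- max(grid$p)
  chunks <- vector("list", nrow(grid) * length(config$methods))
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    cond <- grid[i, ]
    model <- one_factor_model(rep(cond$lambda, cond$p))
    pop <- model$loadings
    reps <- vector("list", cond$n_replications)
    for (r in seq_len(cond$n_replications)) {
      seed <- replication_seed(config$master_seed, cond$lambda, cond$p,
                               cond$N, r)
      reps[[r]] <- tryCatch({
        s <- generate_sample(model, cond$N, seed = seed, case = r)
        moments <- compute_moments(s)
        lapply(config$methods, function(m)
          .fit_record(moments, m, pop, config, max_p))
      }, error = function(e) {
        lapply(config$methods, function(m)
          .error_record(m, conditionMessage(e), max_p, config))
      })
    }
    for (m in seq_along(config$methods)) {
      rows <- do.call(rbind, lapply(reps, `[[`, m))
      rows <- data.frame(method = config$methods[m],
                         lambda = cond$lambda, p = cond$p, N = cond$N,
                         CASE = seq_len(cond$n_replications),
                         seed = vapply(seq_len(cond$n_replications),
                                       function(r) replication_seed(
                                         config$master_seed, cond$lambda,
                                         cond$p, cond$N, r), 0L),
                         rows)
      k <- k + 1L
      chunks[[k]] <- rows
    }
    if (config$verbose) {
      st <- do.call(rbind, lapply(reps, `[[`, 1L))$status
      message(sprintf(
        "condition lambda=%.1f p=%d N=%d: %d reps, %d nonconvergent, %d heywood",
        cond$lambda, cond$p, cond$N, length(st),
        sum(st == "nonconvergent"), sum(st == "heywood")))
    }
  }
  results <- do.call(rbind, chunks[seq_len(k)])
  rownames(results) <- NULL
  attr(results, "master_seed") <- config$master_seed
  if (!is.null(config$output_dir)) .write_study_outputs(results, config)
  results
}

.fit_record <- function(moments, method, pop, config, max_p) {
  fit <- fit_cfa(moments, method = method, se = config$compute_se)
  rec <- data.frame(status = fit$status, converged = fit$converged,
                    n_iterations = fit$n_iterations, f_min = fit$f_min,
                    chi_square = NA_real_, df = fit$df, p_value = NA_real_,
                    rmsea = NA_real_, cfi = NA_real_,
                    avg_loading = NA_real_, ck = NA_real_,
                    mean_se = NA_real_)
  ix <- fit_indices(fit, moments)
  rec$chi_square <- ix$chi_square; rec$p_value <- ix$p_value
  rec$rmsea <- ix$rmsea; rec$cfi <- ix$cfi
  sl <- standardized_loadings(fit, moments)
  rec$avg_loading <- mean(sl)
  rec$ck <- .congruence(sl, pop)
  if (any(is.finite(fit$standard_errors)))
    rec$mean_se <- mean(fit$standard_errors, na.rm = TRUE)
  if (config$keep_loadings)
    rec <- cbind(rec, .loading_cols(fit$loadings, fit$standard_errors, max_p))
  rec
}

.error_record <- function(method, msg, max_p, config) {
  rec <- data.frame(status = "error", converged = FALSE,
                    n_iterations = NA_integer_, f_min = NA_real_,
                    chi_square = NA_real_, df = NA_integer_,
                    p_value = NA_real_, rmsea = NA_real_, cfi = NA_real_,
                    avg_loading = NA_real_, ck = NA_real_,
                    mean_se = NA_real_)
  if (config$keep_loadings)
    rec <- cbind(rec, .loading_cols(numeric(0), numeric(0), max_p))
  rec
}

.loading_cols <- function(lam, se, max_p) {
  out <- as.data.frame(as.list(c(lam, rep(NA_real_, max_p - length(lam)),
                                 se, rep(NA_real_, max_p - length(se)))))
  names(out) <- c(paste0("loading", seq_len(max_p)),
                  paste0("se", seq_len(max_p)))
  out
}

.write_study_outputs <- function(results, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  for (m in config$methods)
    utils::write.csv(results[results$method == m, , drop = FALSE],
                     file.path(config$output_dir,
                               paste0("results_", m, ".csv")),
                     row.names = FALSE)
  for (m in config$methods)
    utils::write.csv(as.data.frame(summarize_study(results, method = m)),
                     file.path(config$output_dir,
                               paste0("summary_", m, ".csv")),
                     row.names = FALSE)
  invisible(NULL)
}

#' Regenerate a single replication of a study
#'
#' Rebuilds the raw data of one `CASE` from its seed substream, so that a
#' stored per-replication result can be audited (for instance rerun through
#' the outlier diagnostics) without regenerating the whole study.
#'
#' @param lambda,p,N Condition labels.
#' @param case Replication index within the condition.
#' @param master_seed The study's master seed.
#' @param results Optional results data frame from [run_study()]; when
#'   given, the matching stored rows are returned alongside and a missing
#'   CASE is an error.
#' @return A list with `sample` (`"cfa_sample"`) and `record` (data frame
#'   of stored rows, or NULL).
#' @export
locate_case <- function(lambda, p, N, case, master_seed = 1L,
                        results = NULL) {
  record <- NULL
  if (!is.null(results)) {
    record <- results[results$lambda == lambda & results$p == p &
                        results$N == N & results$CASE == case, ,
                      drop = FALSE]
    if (!nrow(record))
      stop("CASE ", case, " not found for lambda=", lambda,
           " p=", p, " N=", N)
    master_seed <- attr(results, "master_seed") %||% master_seed
  }
  model <- one_factor_model(rep(lambda, p))
  s <- generate_sample(model, N,
                       seed = replication_seed(master_seed, lambda, p, N,
                                               case),
                       case = case)
  list(sample = s, record = record)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
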