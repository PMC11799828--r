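## Replicated evaluation of the mediation estimators on simulated data:
## mean squared error, confidence-interval length and empirical coverage.

.study_params <- c("TE", "DE", "IE", "rho")

#' Run a replicated simulation study
#'
#' For each replicate, fresh coefficients and samples are generated under
#' the scenario, each requested method is fitted, and squared errors,
#' interval lengths and coverage indicators against the true effects are
#' accumulated. Replicate-level estimation failures are logged and counted,
#' not fatal.
#'
#' @param spec A [scenario_spec()].
#' @param methods Character vector of [mediation_methods()] names, or a
#'   named list of functions `f(data, sets)` returning a data frame with
#'   columns `parameter`, `estimate`, `ci_low`, `ci_high` (hook for custom
#'   estimators).
#' @param n_reps Number of replicates (>= 1).
#' @param seed Optional integer seed; all replicate randomness flows from
#'   it sequentially.
#' @param n_boot Bootstrap replicates for median-based methods (reduced
#'   from the 1000 default of [mr_mediate()] because the bootstrap runs
#'   inside every replicate).
#' @return Object of class `mr_sim_study`: list with `summary` (data frame
#'   method x parameter: `mse`, `mean_ci_length`, `coverage`, `n_reps`,
#'   `n_failed`), `estimates` (array replicate x method x parameter x
#'   statistic), `truth`, `spec`.
#' @export
run_simulation_study <- function(spec, methods = c("Diff-IVW", "Prod-IVW"),
                                 n_reps = 100, seed = NULL, n_boot = 200) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  custom <- is.list(methods)
  m_names <- if (custom) names(methods) else methods
  if (custom && (is.null(m_names) || any(!nzchar(m_names))))
    stop("custom methods must be a named list")
  est <- array(NA_real_,
               dim = c(n_reps, length(m_names), 4, 3),
               dimnames = list(NULL, m_names, .study_params,
                               c("estimate", "ci_low", "ci_high")))
  failures <- stats::setNames(integer(length(m_names)), m_names)
  truth <- NULL
  for (r in seq_len(n_reps)) {
    sim <- generate_scenario(spec)
    if (is.null(truth)) truth <- sim$truth
    for (j in seq_along(m_names)) {
      res <- tryCatch({
        if (custom) {
          e <- methods[[j]](sim$data, sim$sets)
        } else {
          fit <- mr_mediate(sim$data, sim$sets, m_names[j],
                            design = spec$design, n_boot = n_boot)
          e <- fit$estimates
        }
        e[match(.study_params, e$parameter), c("estimate", "ci_low", "ci_high")]
      }, error = function(err) NULL)
      if (is.null(res)) {
        failures[j] <- failures[j] + 1L
      } else {
        est[r, j, , ] <- as.matrix(res)
      }
    }
  }
  tvals <- unlist(truth[c("te", "de", "ie", "rho")])
  rows <- list()
  for (j in seq_along(m_names)) for (p in seq_along(.study_params)) {
    e <- est[, j, p, "estimate"]; lo <- est[, j, p, "ci_low"]
    hi <- est[, j, p, "ci_high"]
    ok <- is.finite(e)
    rows[[length(rows) + 1L]] <- data.frame(
      method = m_names[j], parameter = .study_params[p],
      mse = mean((e[ok] - tvals[p])^2),
      mean_ci_length = mean(hi[ok] - lo[ok]),
      coverage = mean(lo[ok] <= tvals[p] & tvals[p] <= hi[ok]),
      n_reps = sum(ok), n_failed = failures[j],
      stringsAsFactors = FALSE)
  }
  summary_df <- do.call(rbind, rows)
  rownames(summary_df) <- NULL
  structure(list(summary = summary_df, estimates = est, truth = truth,
                 spec = spec, seed = seed),
            class = "mr_sim_study")
}

#' @export
print.mr_sim_study <- function(x, digits = 3, ...) {
  cat(sprintf("Simulation study: %s, %d replicate(s), n = %d per sample\n",
              x$spec$scenario, max(x$summary$n_reps + x$summary$n_failed),
              x$spec$n))
  df <- x$summary
  df$mse <- signif(df$mse, digits)
  df$mean_ci_length <- signif(df$mean_ci_length, digits)
  df$coverage <- round(df$coverage, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a simulation study result as TSV and JSON
#'
#' @param study An `mr_sim_study` object.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir, prefix = "study") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(prefix, ".tsv"))
  js <- file.path(dir, paste0(prefix, ".json"))
  utils::write.table(study$summary, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  payload <- list(scenario = study$spec$scenario, n = study$spec$n,
                  design = study$spec$design, seed = study$seed,
                  truth = study$truth, summary = study$summary)
  writeLines(jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                              digits = NA, pretty = TRUE), js)
  invisible(c(tsv = tsv, json = js))
}
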