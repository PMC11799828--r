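## MR-based mediation analysis: compose UVMR and MVMR fits into the eight
## difference- and product-method estimators of the total effect (TE),
## direct effect (DE), indirect effect (IE) and mediation proportion (rho).

#' Names of the available mediation methods
#'
#' Difference methods estimate the direct effect by multivariable MR and the
#' indirect effect by subtraction; product methods estimate the
#' exposure-mediator and mediator-outcome effects separately and multiply.
#' The `0`-suffixed variants are the legacy procedures that predate double
#' clumping of the combined instrument sets: the total effect (and, for the
#' product variant, the exposure-mediator effect) is estimated on the full
#' exposure instrument set `GX` rather than the pruned `GX'`, the difference
#' variant assumes zero covariance between the total- and direct-effect
#' estimators, and the legacy product variant takes the mediator-outcome
#' effect from the multivariable fit.
#'
#' @return Character vector of the eight method names.
#' @export
mediation_methods <- function() {
  c("Diff-IVW0", "Diff-IVW", "Diff-Egger", "Diff-Median",
    "Prod-IVW0", "Prod-IVW", "Prod-Egger", "Prod-Median")
}

.method_spec <- function(method) {
  method <- match.arg(method, mediation_methods())
  framework <- if (startsWith(method, "Diff")) "difference" else "product"
  estimator <- switch(sub(".*-", "", method),
                      IVW0 = "ivw", IVW = "ivw",
                      Egger = "egger", Median = "median")
  list(method = method, framework = framework, estimator = estimator,
       legacy = endsWith(method, "IVW0"))
}

.subset_sets <- function(sets, data) {
  ok <- data$snp_id
  s <- lapply(sets[c("gx", "gm", "gx_prime", "gm_prime")], intersect, ok)
  if (!length(s$gx_prime)) stop("no GX' instruments present in the data")
  if (!length(s$gm_prime)) stop("no GM' instruments present in the data")
  s
}

#' Covariance between total- and direct-effect estimators
#'
#' Both the univariable total-effect estimator and the multivariable
#' direct-effect estimator are linear in the SNP-outcome association
#' statistics. In the two-sample setting the outcome statistics are the only
#' quantities the two fits share, so their covariance reduces to a sum over
#' the shared SNPs of the product of the two linear weight vectors times the
#' squared outcome standard errors. No heterogeneity inflation is applied to
#' the covariance: under Monte-Carlo regeneration of the outcome statistics
#' the unscaled sum is the unbiased estimate, whereas scaling by the clamped
#' heterogeneity parameters biases it upward under the null (the variances
#' entering the indirect-effect variance keep their own multiplicative
#' random-effects scaling).
#'
#' @param total_fit A `uvmr_fit` (IVW or Egger) with linear weights.
#' @param direct_fit An `mvmr_fit` (IVW or Egger) with linear weights.
#' @return The covariance estimate (0 when the fits share no SNPs).
#' @export
cov_total_direct <- function(total_fit, direct_fit) {
  if (is.null(total_fit$weights) || is.null(total_fit$snps))
    stop("total_fit does not expose linear weights")
  if (is.null(direct_fit$weights_delta) || is.null(direct_fit$snps))
    stop("direct_fit does not expose linear weights")
  shared <- intersect(total_fit$snps, direct_fit$snps)
  if (!length(shared)) return(0)
  it <- match(shared, total_fit$snps)
  id <- match(shared, direct_fit$snps)
  sum(total_fit$weights[it] * direct_fit$weights_delta[id] *
      direct_fit$se_out[id]^2)
}

## Delta-method variance for rho = 1 - de/te (difference framework).
.rho_var_diff <- function(te, de, v_te, v_de, cov_td) {
  (de / te)^2 * (v_de / de^2 + v_te / te^2 - 2 * cov_td / (de * te))
}

## Delta-method variance for rho = alpha*beta/te (product framework,
## mutually independent components).
.rho_var_prod <- function(alpha, beta, te, v_a, v_b, v_te) {
  rho <- alpha * beta / te
  rho^2 * (v_a / alpha^2 + v_b / beta^2 + v_te / te^2)
}

.param_row <- function(estimate, se, conf_level, ci = NULL) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  estimate <- unname(estimate); se <- unname(se)
  if (is.null(ci)) ci <- c(estimate - z * se, estimate + z * se)
  data.frame(estimate = estimate, se = se,
             ci_low = unname(ci[1]), ci_high = unname(ci[2]))
}

## Point estimates only (no inference) -- used by the parametric bootstrap.
.mediation_points <- function(data, sets, spec) {
  s <- .subset_sets(sets, data)
  union_snps <- union(s$gx_prime, s$gm_prime)
  te_set <- if (spec$legacy) s$gx else s$gx_prime
  point_uvmr <- function(snps, exp_col, out_col) {
    d <- data[data$snp_id %in% snps, , drop = FALSE]
    se_out <- d[[paste0("se_", sub("_hat", "", out_col))]]
    switch(spec$estimator,
      ivw = { w <- 1 / se_out^2
              sum(w * d[[exp_col]] * d[[out_col]]) / sum(w * d[[exp_col]]^2) },
      egger = { flip <- ifelse(d[[exp_col]] < 0, -1, 1)
                bx <- flip * d[[exp_col]]; by <- flip * d[[out_col]]
                w <- 1 / se_out^2
                X <- cbind(1, bx)
                drop(solve(t(X * w) %*% X, t(X * w) %*% by))[2] },
      median = { keep <- d[[exp_col]] != 0
                 r <- d[[out_col]][keep] / d[[exp_col]][keep]
                 rse <- se_out[keep] / abs(d[[exp_col]][keep])
                 .weighted_median(r, 1 / rse^2) })
  }
  te <- point_uvmr(te_set, "a_hat", "pi_hat")
  if (spec$framework == "difference") {
    d <- data[data$snp_id %in% union_snps, , drop = FALSE]
    w <- 1 / d$se_pi^2
    de <- switch(spec$estimator,
      ivw = { A <- cbind(d$a_hat, d$b_hat)
              drop(solve(t(A * w) %*% A, t(A * w) %*% d$pi_hat))[1] },
      egger = { flip <- ifelse(d$a_hat < 0, -1, 1)
                A <- cbind(1, flip * d$a_hat, flip * d$b_hat)
                drop(solve(t(A * w) %*% A, t(A * w) %*% (flip * d$pi_hat)))[2] },
      median = .l1_fit(d$a_hat, d$b_hat, d$pi_hat, w)[1])
    ie <- te - de
  } else {
    alpha <- point_uvmr(if (spec$legacy) s$gx else s$gx_prime, "a_hat", "b_hat")
    beta <- if (spec$legacy) {
      d <- data[data$snp_id %in% union_snps, , drop = FALSE]
      w <- 1 / d$se_pi^2
      A <- cbind(d$a_hat, d$b_hat)
      drop(solve(t(A * w) %*% A, t(A * w) %*% d$pi_hat))[2]
    } else point_uvmr(s$gm_prime, "b_hat", "pi_hat")
    ie <- alpha * beta
    de <- te - ie
  }
  c(te = unname(te), de = unname(de), ie = unname(ie),
    rho = if (te == 0) NA_real_ else unname(ie / te))
}

#' Parametric bootstrap confidence intervals for a mediation method
#'
#' Each replicate redraws every summary statistic from a normal distribution
#' centred at its observed value with its reported standard error,
#' independently across the exposure, mediator and outcome tables (a
#' three-sample assumption), re-estimates the method's point estimates, and
#' takes percentile intervals. Replicates where estimation fails are dropped
#' and counted; more than 20 percent failures is an error.
#'
#' @param data A `harmonized_data` table.
#' @param sets An [instrument_sets()] object (or plain list with the same
#'   fields).
#' @param method One of [mediation_methods()].
#' @param n_boot Number of replicates (>= 100).
#' @param seed Optional integer seed applied locally.
#' @param conf_level Confidence level for the percentile intervals.
#' @return List with `ci` (matrix, rows TE/DE/IE/rho), `se` (bootstrap
#'   standard deviations), `replicates` (matrix of per-replicate estimates)
#'   and `n_failed`.
#' @export
parametric_bootstrap_ci <- function(data, sets, method, n_boot = 1000,
                                    seed = NULL, conf_level = 0.95) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  spec <- .method_spec(method)
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(data)
  reps <- matrix(NA_real_, n_boot, 4,
                 dimnames = list(NULL, c("TE", "DE", "IE", "rho")))
  for (i in seq_len(n_boot)) {
    db <- data
    db$a_hat <- stats::rnorm(k, data$a_hat, data$se_a)
    db$b_hat <- stats::rnorm(k, data$b_hat, data$se_b)
    db$pi_hat <- stats::rnorm(k, data$pi_hat, data$se_pi)
    est <- tryCatch(.mediation_points(db, sets, spec),
                    error = function(e) rep(NA_real_, 4))
    reps[i, ] <- est
  }
  ok <- stats::complete.cases(reps)
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * n_boot)
    stop("parametric bootstrap: ", n_failed, " of ", n_boot,
         " replicates failed estimation")
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  ci <- t(apply(reps[ok, , drop = FALSE], 2, stats::quantile, probs = probs))
  list(ci = ci, se = apply(reps[ok, , drop = FALSE], 2, stats::sd),
       replicates = reps, n_failed = n_failed)
}

#' MR-based mediation analysis
#'
#' Fits one of the eight summary-data MR mediation estimators, returning the
#' total effect (TE), direct effect (DE), indirect effect (IE) and mediation
#' proportion (rho) with standard errors and confidence intervals.
#'
#' Difference methods (`Diff-*`) estimate TE by univariable MR on the pruned
#' exposure instruments `GX'` (the legacy `Diff-IVW0` uses the full `GX`)
#' and DE by multivariable MR on `GX' U GM'`; IE = TE - DE with
#' `Var(IE) = Var(TE) + Var(DE) - 2 Cov(TE, DE)`, the covariance
#' reconstructed by [cov_total_direct()] (assumed zero for `Diff-IVW0`).
#' `Diff-Median` instead draws percentile intervals from a parametric
#' bootstrap of all summary statistics. Product methods (`Prod-*`) estimate
#' the exposure-mediator effect alpha on `GX'` and the mediator-outcome
#' effect beta on `GM'` (the legacy `Prod-IVW0` instead estimates alpha on
#' the unpruned `GX` and takes beta from the multivariable fit);
#' IE = alpha*beta with delta-method variance
#' `alpha^2 Var(beta) + beta^2 Var(alpha)`, and DE = TE - IE with variances
#' added (components estimated on independent samples). rho is IE/TE
#' (equivalently 1 - DE/TE) with delta-method variance.
#'
#' @param data A `harmonized_data` table from [harmonize()] or
#'   [generate_scenario()] with columns `snp_id`, `a_hat`, `se_a`, `b_hat`,
#'   `se_b`, `pi_hat`, `se_pi`.
#' @param sets An [instrument_sets()] object; only SNPs present in `data`
#'   are used.
#' @param method One of [mediation_methods()].
#' @param design `"two-sample"` (exposure and mediator statistics from one
#'   sample, outcome from another) or `"three-sample"`; recorded in the
#'   result and asserted for the bootstrap-based methods, not inferable
#'   from the data.
#' @param n_boot Bootstrap replicates for median-based methods.
#' @param seed Optional integer seed; required for reproducibility whenever
#'   the method involves bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `mr_mediation`: list with `method`,
#'   `estimates` (data frame with rows TE, DE, IE, rho), `cov_total_direct`,
#'   `components` (the underlying fits), `design`, `n_boot`, `seed`.
#' @examples
#' sim <- generate_scenario(scenario_spec("S1", n = 2000), seed = 1)
#' fit <- mr_mediate(sim$data, sim$sets, "Diff-IVW")
#' coef(fit)
#' @export
mr_mediate <- function(data, sets, method = "Diff-IVW",
                       design = c("two-sample", "three-sample"),
                       n_boot = 1000, seed = NULL, conf_level = 0.95) {
  spec <- .method_spec(method)
  design <- match.arg(design)
  if (!is.null(seed)) set.seed(seed)
  s <- .subset_sets(sets, data)
  union_snps <- union(s$gx_prime, s$gm_prime)
  te_set <- if (spec$legacy) s$gx else s$gx_prime
  components <- list()
  cov_td <- NA_real_

  if (spec$framework == "difference" && spec$estimator == "median") {
    te_fit <- .uvmr_on(data, te_set, "median", "a_hat", "pi_hat",
                       se_exp_col = "se_a", n_boot = n_boot)
    de_fit <- .mvmr_on(data, union_snps, "median", n_boot = n_boot)
    pts <- c(te = te_fit$estimate, de = de_fit$delta)
    boot <- parametric_bootstrap_ci(data, sets, method, n_boot = n_boot,
                                    conf_level = conf_level)
    est <- rbind(
      TE = .param_row(pts["te"], boot$se["TE"], conf_level, boot$ci["TE", ]),
      DE = .param_row(pts["de"], boot$se["DE"], conf_level, boot$ci["DE", ]),
      IE = .param_row(pts["te"] - pts["de"], boot$se["IE"], conf_level,
                      boot$ci["IE", ]),
      rho = .param_row(1 - pts["de"] / pts["te"], boot$se["rho"], conf_level,
                       boot$ci["rho", ]))
    components <- list(total = te_fit, direct = de_fit, bootstrap = boot)
  } else if (spec$framework == "difference") {
    te_fit <- .uvmr_on(data, te_set, spec$estimator, "a_hat", "pi_hat")
    de_fit <- .mvmr_on(data, union_snps, spec$estimator)
    cov_td <- if (spec$legacy) 0 else cov_total_direct(te_fit, de_fit)
    te <- te_fit$estimate; de <- de_fit$delta
    v_te <- te_fit$se^2; v_de <- de_fit$se_delta^2
    ie <- te - de
    v_ie <- v_te + v_de - 2 * cov_td
    if (v_ie < 0) { warning("negative Var(IE) truncated to 0"); v_ie <- 0 }
    if (te == 0) {
      warning("total effect estimated as exactly 0; rho undefined")
      rho <- NA_real_; v_rho <- NA_real_
    } else {
      rho <- 1 - de / te
      v_rho <- .rho_var_diff(te, de, v_te, v_de, cov_td)
    }
    est <- rbind(
      TE = .param_row(te, sqrt(v_te), conf_level),
      DE = .param_row(de, sqrt(v_de), conf_level),
      IE = .param_row(ie, sqrt(v_ie), conf_level),
      rho = .param_row(rho, sqrt(v_rho), conf_level))
    components <- list(total = te_fit, direct = de_fit)
  } else {
    ## product framework
    te_fit <- .uvmr_on(data, te_set, spec$estimator, "a_hat", "pi_hat",
                       se_exp_col = "se_a", n_boot = n_boot)
    alpha_set <- if (spec$legacy) s$gx else s$gx_prime
    alpha_fit <- .uvmr_on(data, alpha_set, spec$estimator, "a_hat", "b_hat",
                          se_exp_col = "se_a", n_boot = n_boot)
    if (spec$legacy) {
      mv <- .mvmr_on(data, union_snps, "ivw")
      beta_est <- mv$beta; v_b <- mv$se_beta^2
      beta_fit <- mv
    } else {
      beta_fit <- .uvmr_on(data, s$gm_prime, spec$estimator, "b_hat", "pi_hat",
                           se_exp_col = "se_b", n_boot = n_boot)
      beta_est <- beta_fit$estimate; v_b <- beta_fit$se^2
    }
    te <- te_fit$estimate; v_te <- te_fit$se^2
    alpha <- alpha_fit$estimate; v_a <- alpha_fit$se^2
    ie <- alpha * beta_est
    v_ie <- alpha^2 * v_b + beta_est^2 * v_a
    de <- te - ie
    v_de <- v_te + v_ie
    if (te == 0) {
      warning("total effect estimated as exactly 0; rho undefined")
      rho <- NA_real_; v_rho <- NA_real_
    } else {
      rho <- ie / te
      v_rho <- .rho_var_prod(alpha, beta_est, te, v_a, v_b, v_te)
    }
    est <- rbind(
      TE = .param_row(te, sqrt(v_te), conf_level),
      DE = .param_row(de, sqrt(v_de), conf_level),
      IE = .param_row(ie, sqrt(v_ie), conf_level),
      rho = .param_row(rho, sqrt(v_rho), conf_level))
    components <- list(total = te_fit, alpha = alpha_fit, beta = beta_fit)
  }
  est <- cbind(parameter = rownames(est), est)
  rownames(est) <- NULL
  structure(list(method = spec$method, estimates = est,
                 cov_total_direct = cov_td, components = components,
                 design = design, n_boot = n_boot, seed = seed,
                 conf_level = conf_level, call = match.call()),
            class = "mr_mediation")
}

#' @export
print.mr_mediation <- function(x, digits = 4, ...) {
  cat("MR-based mediation analysis:", x$method,
      sprintf("(%s design)\n", x$design))
  e <- x$estimates
  tab <- data.frame(
    estimate = format(e$estimate, digits = digits),
    se = format(e$se, digits = digits),
    ci = sprintf("[%s, %s]", format(e$ci_low, digits = digits),
                 format(e$ci_high, digits = digits)),
    row.names = e$parameter)
  names(tab)[3] <- sprintf("%d%% CI", round(100 * x$conf_level))
  print(tab)
  invisible(x)
}

#' @export
summary.mr_mediation <- function(object, ...) {
  print(object)
  if (is.finite(object$cov_total_direct))
    cat(sprintf("Cov(TE-hat, DE-hat) = %s\n",
                format(object$cov_total_direct, digits = 4)))
  for (nm in names(object$components)) {
    comp <- object$components[[nm]]
    if (inherits(comp, c("uvmr_fit", "mvmr_fit"))) {
      cat("\ncomponent [", nm, "]: ", sep = "")
      print(comp)
    }
  }
  invisible(object)
}

#' @export
coef.mr_mediation <- function(object, ...) {
  stats::setNames(object$estimates$estimate, object$estimates$parameter)
}

#' @export
confint.mr_mediation <- function(object, parm, level, ...) {
  m <- as.matrix(object$estimates[, c("ci_low", "ci_high")])
  rownames(m) <- object$estimates$parameter
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' Run several mediation methods on the same harmonized data
#'
#' @inheritParams mr_mediate
#' @param methods Character vector of method names (default: the three
#'   recommended methods `Diff-IVW`, `Prod-IVW`, `Prod-Median`).
#' @return Named list of `mr_mediation` objects, class `mr_mediation_list`.
#' @export
mr_mediate_all <- function(data, sets,
                           methods = c("Diff-IVW", "Prod-IVW", "Prod-Median"),
                           design = c("two-sample", "three-sample"),
                           n_boot = 1000, seed = NULL, conf_level = 0.95) {
  design <- match.arg(design)
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(methods, function(m)
    mr_mediate(data, sets, m, design = design, n_boot = n_boot,
               conf_level = conf_level))
  names(fits) <- methods
  structure(fits, class = "mr_mediation_list")
}

#' @export
print.mr_mediation_list <- function(x, ...) {
  print(mediation_table(x))
  invisible(x)
}

#' Tabulate mediation results, one row per method
#'
#' Formats a set of fits as a method-by-parameter table with confidence
#' intervals, optionally exponentiating TE, DE and IE into odds ratios for
#' binary outcomes (the mediation proportion stays on the proportion scale).
#'
#' @param fits An `mr_mediation_list` (or list of `mr_mediation` objects).
#' @param exponentiate Exponentiate TE/DE/IE estimates and CI bounds.
#' @param digits Significant digits in the formatted columns.
#' @return Data frame with one row per method.
#' @export
mediation_table <- function(fits, exponentiate = FALSE, digits = 3) {
  rows <- lapply(fits, function(f) {
    e <- f$estimates
    fmt <- function(p) {
      r <- e[e$parameter == p, ]
      tr <- if (exponentiate && p != "rho") exp else identity
      sprintf("%s (%s, %s)", format(tr(r$estimate), digits = digits),
              format(tr(r$ci_low), digits = digits),
              format(tr(r$ci_high), digits = digits))
    }
    data.frame(method = f$method, TE = fmt("TE"), DE = fmt("DE"),
               IE = fmt("IE"), rho = fmt("rho"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize mediation fits to JSON
#'
#' @param fits An `mr_mediation_list` or single `mr_mediation` object.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
mediation_json <- function(fits, path = NULL) {
  if (inherits(fits, "mr_mediation")) fits <- list(fits)
  payload <- lapply(unname(fits), function(f) {
    list(method = f$method, design = f$design,
         estimates = f$estimates,
         cov_total_direct = f$cov_total_direct,
         n_boot = f$n_boot, seed = f$seed)
  })
  js <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
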