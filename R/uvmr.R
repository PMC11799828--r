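## Univariable MR estimators: IVW, Egger, weighted median.
##
## Each fit returns a "uvmr_fit" object carrying, besides the estimate and
## multiplicative random-effects standard error, the linear representation
## of the estimator in the SNP-outcome statistics (weights such that
## estimate = sum(weights * outcome_beta)) where one exists; the mediation
## layer uses it to reconstruct covariances between estimators.

.new_uvmr_fit <- function(method, estimate, se, n_snps, phi,
                          snps = NULL, weights = NULL, se_out = NULL,
                          intercept = NULL, intercept_se = NULL,
                          conf_level = 0.95, extra = list()) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  estimate <- unname(estimate); se <- unname(se)
  if (!is.null(intercept)) intercept <- unname(intercept)
  if (!is.null(intercept_se)) intercept_se <- unname(intercept_se)
  structure(c(list(
    method = method, estimate = estimate, se = se,
    ci_low = estimate - z * se, ci_high = estimate + z * se,
    n_snps = n_snps, phi = phi,
    snps = snps, weights = weights, se_out = se_out,
    intercept = intercept, intercept_se = intercept_se,
    conf_level = conf_level), extra),
    class = "uvmr_fit")
}

#' @export
print.uvmr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s estimate (K = %d SNPs):\n", x$method, x$n_snps))
  cat(sprintf("  estimate %s  se %s  %d%% CI [%s, %s]  phi %s\n",
              format(x$estimate, digits = digits),
              format(x$se, digits = digits),
              round(100 * x$conf_level),
              format(x$ci_low, digits = digits),
              format(x$ci_high, digits = digits),
              format(x$phi, digits = digits)))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept %s (se %s)\n",
                format(x$intercept, digits = digits),
                format(x$intercept_se, digits = digits)))
  invisible(x)
}

.check_assoc <- function(beta_exp, beta_out, se_out, min_k, method) {
  stopifnot(length(beta_exp) == length(beta_out),
            length(beta_out) == length(se_out))
  if (any(!is.finite(beta_exp)) || any(!is.finite(beta_out)) ||
      any(!is.finite(se_out)))
    stop(method, ": non-finite association statistics")
  if (any(se_out <= 0)) stop(method, ": all outcome standard errors must be > 0")
  if (length(beta_exp) < min_k)
    stop(method, " requires at least ", min_k, " SNPs, got ", length(beta_exp))
  invisible(TRUE)
}

#' Per-SNP Wald ratio estimates
#'
#' Computes the ratio estimate `beta_out / beta_exp` per SNP together with
#' its first-order standard error `se_out / |beta_exp|` (exposure
#' associations treated as measured without error). SNPs with a zero
#' exposure association are dropped with a warning.
#'
#' @param beta_exp,beta_out Numeric vectors of SNP-exposure and SNP-outcome
#'   association estimates.
#' @param se_out Standard errors of `beta_out`.
#' @return Data frame with columns `ratio` and `ratio_se` (and the surviving
#'   `index` into the input).
#' @export
ratio_estimates <- function(beta_exp, beta_out, se_out) {
  .check_assoc(beta_exp, beta_out, se_out, 1L, "ratio_estimates")
  keep <- beta_exp != 0
  if (!any(keep)) stop("all SNPs have zero exposure association")
  if (any(!keep)) warning(sum(!keep), " SNP(s) with zero exposure association dropped")
  data.frame(index = which(keep),
             ratio = beta_out[keep] / beta_exp[keep],
             ratio_se = se_out[keep] / abs(beta_exp[keep]))
}

#' Inverse-variance weighted univariable MR
#'
#' Weighted least squares of the SNP-outcome associations on the
#' SNP-exposure associations through the origin, with weights
#' `1/se_out^2`. The standard error uses the multiplicative random-effects
#' model: the fixed-effect variance `1/sum(beta_exp^2/se_out^2)` is scaled
#' by the heterogeneity parameter `phi = max(1, Q/(K-1))`, where `Q` is the
#' weighted residual sum of squares.
#'
#' @inheritParams ratio_estimates
#' @param snp_id Optional identifiers carried through to the fit (used for
#'   covariance reconstruction between estimators sharing SNPs).
#' @param conf_level Confidence level for the normal-theory interval.
#' @return A `uvmr_fit` object.
#' @examples
#' mr_ivw(c(1, 1), c(1, 3), c(1, 1))  # estimate 2, Q = 2, phi = 2, se = 1
#' @export
mr_ivw <- function(beta_exp, beta_out, se_out, snp_id = NULL,
                   conf_level = 0.95) {
  .check_assoc(beta_exp, beta_out, se_out, 1L, "mr_ivw")
  k <- length(beta_exp)
  w <- 1 / se_out^2
  denom <- sum(w * beta_exp^2)
  if (denom <= 0) stop("mr_ivw: degenerate design (all exposure betas zero)")
  est <- sum(w * beta_exp * beta_out) / denom
  Q <- sum(w * (beta_out - est * beta_exp)^2)
  phi <- if (k >= 2) max(1, Q / (k - 1)) else 1
  se <- sqrt(phi / denom)
  .new_uvmr_fit("MR-IVW", est, se, k, phi,
                snps = snp_id, weights = w * beta_exp / denom,
                se_out = se_out, conf_level = conf_level,
                extra = list(Q = Q))
}

#' MR-Egger regression
#'
#' Weighted least squares of the SNP-outcome on the SNP-exposure
#' associations with an intercept, after orienting every SNP so its exposure
#' association is non-negative. The slope estimates the causal effect; the
#' intercept the average directional pleiotropy (InSIDE assumption). Both
#' standard errors are scaled by `phi = max(1, Q/(K-2))`.
#'
#' @inheritParams mr_ivw
#' @return A `uvmr_fit` object with `intercept`, `intercept_se` fields.
#' @export
mr_egger <- function(beta_exp, beta_out, se_out, snp_id = NULL,
                     conf_level = 0.95) {
  .check_assoc(beta_exp, beta_out, se_out, 3L, "mr_egger")
  k <- length(beta_exp)
  flip <- ifelse(beta_exp < 0, -1, 1)
  bx <- flip * beta_exp; by <- flip * beta_out
  if (length(unique(bx)) < 2L)
    stop("mr_egger: exposure associations collinear with the intercept")
  w <- 1 / se_out^2
  X <- cbind(intercept = 1, slope = bx)
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  H <- solve(XtWX, XtW)          # 2 x K: coefficients = H %*% by
  coefs <- drop(H %*% by)
  resid <- by - drop(X %*% coefs)
  Q <- sum(w * resid^2)
  phi <- max(1, Q / (k - 2))
  covb <- phi * solve(XtWX)
  # linear weights on the *original* outcome betas include the orientation
  .new_uvmr_fit("MR-Egger", coefs[2], sqrt(covb[2, 2]), k, phi,
                snps = snp_id, weights = drop(H[2, ]) * flip,
                se_out = se_out,
                intercept = coefs[1], intercept_se = sqrt(covb[1, 1]),
                conf_level = conf_level, extra = list(Q = Q))
}

## Weighted median of values x with positive weights w: sort, form
## midpoint-cumulative standardized weights and interpolate at 1/2.
.weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(x[1])
  n <- length(x)
  if (0.5 >= s[n]) return(x[n])
  j <- findInterval(0.5, s)
  x[j] + (0.5 - s[j]) / (s[j + 1] - s[j]) * (x[j + 1] - x[j])
}

#' Weighted median univariable MR
#'
#' The weighted median of the per-SNP Wald ratios with inverse-variance
#' weights `1/ratio_se^2`, consistent when more than half of the weight
#' comes from valid instruments. The standard error is obtained by a
#' parametric bootstrap: each replicate redraws the summary statistics from
#' normal distributions centred at their observed values with their reported
#' standard errors and recomputes the weighted median.
#'
#' @inheritParams mr_ivw
#' @param se_exp Standard errors of the SNP-exposure associations; when
#'   supplied the bootstrap perturbs the exposure side too, otherwise the
#'   exposure associations are held fixed.
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Optional integer seed applied locally to the bootstrap.
#' @return A `uvmr_fit` object (field `boot` holds the replicate estimates).
#' @export
mr_median <- function(beta_exp, beta_out, se_out, se_exp = NULL,
                      n_boot = 1000, seed = NULL, conf_level = 0.95) {
  .check_assoc(beta_exp, beta_out, se_out, 3L, "mr_median")
  if (n_boot < 100) stop("mr_median: n_boot must be >= 100")
  if (!is.null(se_exp)) stopifnot(length(se_exp) == length(beta_exp),
                                  all(se_exp > 0))
  point <- function(bx, by) {
    keep <- bx != 0
    r <- by[keep] / bx[keep]
    rse <- se_out[keep] / abs(bx[keep])
    .weighted_median(r, 1 / rse^2)
  }
  est <- point(beta_exp, beta_out)
  if (!is.null(seed)) set.seed(seed)
  k <- length(beta_exp)
  boot <- vapply(seq_len(n_boot), function(i) {
    bx <- if (is.null(se_exp)) beta_exp else stats::rnorm(k, beta_exp, se_exp)
    by <- stats::rnorm(k, beta_out, se_out)
    point(bx, by)
  }, numeric(1))
  se <- stats::sd(boot)
  .new_uvmr_fit("MR-Median", est, se, k, 1,
                snps = NULL, weights = NULL, se_out = se_out,
                conf_level = conf_level, extra = list(boot = boot))
}

## Convenience: fit a UVMR estimator by name on columns of a harmonized
## table restricted to a SNP set.
.uvmr_on <- function(data, snps, estimator, exp_col, out_col,
                     se_exp_col = NULL, n_boot = 1000, seed = NULL) {
  d <- data[data$snp_id %in% snps, , drop = FALSE]
  if (!nrow(d)) stop("no SNPs available for UVMR fit")
  se_out_col <- paste0("se_", sub("_hat", "", out_col))
  args <- list(beta_exp = d[[exp_col]], beta_out = d[[out_col]],
               se_out = d[[se_out_col]], snp_id = d$snp_id)
  switch(estimator,
    ivw = do.call(mr_ivw, args),
    egger = do.call(mr_egger, args),
    median = {
      args$snp_id <- NULL
      args$se_exp <- if (!is.null(se_exp_col)) d[[se_exp_col]]
      do.call(mr_median, c(args, list(n_boot = n_boot, seed = seed)))
    },
    stop("unknown estimator: ", estimator))
}
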