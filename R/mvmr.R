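## Multivariable MR: regress SNP-outcome associations jointly on the
## SNP-exposure and SNP-mediator associations over the union of the pruned
## instrument sets.

.new_mvmr_fit <- function(method, delta, beta, cov, n_snps, phi,
                          snps = NULL, weights_delta = NULL,
                          weights_beta = NULL, se_out = NULL,
                          intercept = NULL, intercept_se = NULL,
                          conf_level = 0.95, extra = list()) {
  delta <- unname(delta); beta <- unname(beta)
  if (!is.null(intercept)) intercept <- unname(intercept)
  structure(c(list(
    method = method, delta = delta, beta = beta, cov = cov,
    se_delta = sqrt(cov[1, 1]), se_beta = sqrt(cov[2, 2]),
    n_snps = n_snps, phi = phi, snps = snps,
    weights_delta = weights_delta, weights_beta = weights_beta,
    se_out = se_out, intercept = intercept, intercept_se = intercept_se,
    conf_level = conf_level), extra),
    class = "mvmr_fit")
}

#' @export
print.mvmr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit (K = %d SNPs):\n", x$method, x$n_snps))
  cat(sprintf("  direct effect delta %s (se %s)\n",
              format(x$delta, digits = digits),
              format(x$se_delta, digits = digits)))
  cat(sprintf("  mediator effect beta %s (se %s)\n",
              format(x$beta, digits = digits),
              format(x$se_beta, digits = digits)))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept %s (se %s)\n",
                format(x$intercept, digits = digits),
                format(x$intercept_se, digits = digits)))
  cat(sprintf("  phi %s\n", format(x$phi, digits = digits)))
  invisible(x)
}

.check_mvmr <- function(bx, bm, by, se, min_k, method) {
  stopifnot(length(bx) == length(bm), length(bm) == length(by),
            length(by) == length(se))
  if (any(!is.finite(c(bx, bm, by, se))))
    stop(method, ": non-finite association statistics")
  if (any(se <= 0)) stop(method, ": outcome standard errors must be > 0")
  if (length(bx) < min_k)
    stop(method, " requires at least ", min_k, " SNPs, got ", length(bx))
  invisible(TRUE)
}

.rank_check <- function(M, method) {
  qd <- qr(M)
  if (qd$rank < ncol(M)) {
    sv <- svd(M, nu = 0, nv = 0)$d
    stop(method, ": rank-deficient design (condition number ",
         format(max(sv) / max(min(sv), .Machine$double.eps), digits = 3), ")")
  }
}

#' Multivariable IVW regression
#'
#' Weighted least squares without intercept of the SNP-outcome associations
#' on the SNP-exposure and SNP-mediator associations, weights
#' `1/se_out^2`. The coefficient on the exposure column is the direct
#' effect; the coefficient on the mediator column is the mediator-outcome
#' effect. The coefficient covariance is `phi * (A'WA)^{-1}` with
#' `phi = max(1, Q/(K-2))`.
#'
#' @param beta_x,beta_m SNP-exposure and SNP-mediator association estimates
#'   over the combined instrument set.
#' @param beta_out,se_out SNP-outcome association estimates and standard
#'   errors.
#' @param snp_id Optional identifiers carried through to the fit.
#' @param conf_level Confidence level recorded on the fit.
#' @return An `mvmr_fit` object; fields `weights_delta`/`weights_beta` hold
#'   the linear weight vectors such that `delta = sum(weights_delta *
#'   beta_out)` exactly.
#' @examples
#' mvmr_ivw(c(1, 1, 0), c(0, 1, 1), c(1, 2, 1), c(1, 1, 1))
#' @export
mvmr_ivw <- function(beta_x, beta_m, beta_out, se_out, snp_id = NULL,
                     conf_level = 0.95) {
  .check_mvmr(beta_x, beta_m, beta_out, se_out, 3L, "mvmr_ivw")
  k <- length(beta_x)
  w <- 1 / se_out^2
  A <- cbind(delta = beta_x, beta = beta_m)
  .rank_check(A * sqrt(w), "mvmr_ivw")
  AtW <- t(A * w)
  AtWA <- AtW %*% A
  H <- solve(AtWA, AtW)               # 2 x K
  coefs <- drop(H %*% beta_out)
  resid <- beta_out - drop(A %*% coefs)
  Q <- sum(w * resid^2)
  phi <- max(1, Q / (k - 2))
  covb <- phi * solve(AtWA)
  .new_mvmr_fit("MVMR-IVW", coefs[1], coefs[2], covb, k, phi,
                snps = snp_id, weights_delta = drop(H[1, ]),
                weights_beta = drop(H[2, ]), se_out = se_out,
                conf_level = conf_level, extra = list(Q = Q))
}

#' Multivariable Egger regression
#'
#' As [mvmr_ivw()] but with an intercept term capturing average directional
#' pleiotropy, after orienting every SNP so its exposure association is
#' non-negative (the mediator and outcome associations are flipped with
#' it). `phi = max(1, Q/(K-3))`.
#'
#' @inheritParams mvmr_ivw
#' @return An `mvmr_fit` object with `intercept`, `intercept_se`.
#' @export
mvmr_egger <- function(beta_x, beta_m, beta_out, se_out, snp_id = NULL,
                       conf_level = 0.95) {
  .check_mvmr(beta_x, beta_m, beta_out, se_out, 4L, "mvmr_egger")
  k <- length(beta_x)
  flip <- ifelse(beta_x < 0, -1, 1)
  bx <- flip * beta_x; bm <- flip * beta_m; by <- flip * beta_out
  w <- 1 / se_out^2
  A <- cbind(intercept = 1, delta = bx, beta = bm)
  .rank_check(A * sqrt(w), "mvmr_egger")
  AtW <- t(A * w)
  AtWA <- AtW %*% A
  H <- solve(AtWA, AtW)               # 3 x K
  coefs <- drop(H %*% by)
  resid <- by - drop(A %*% coefs)
  Q <- sum(w * resid^2)
  phi <- max(1, Q / (k - 3))
  covb <- phi * solve(AtWA)
  .new_mvmr_fit("MVMR-Egger", coefs[2], coefs[3], covb[2:3, 2:3], k, phi,
                snps = snp_id,
                weights_delta = drop(H[2, ]) * flip,
                weights_beta = drop(H[3, ]) * flip,
                se_out = se_out,
                intercept = coefs[1], intercept_se = sqrt(covb[1, 1]),
                conf_level = conf_level, extra = list(Q = Q))
}

## Weighted L1 objective for the median-type MVMR fit.
.l1_objective <- function(par, bx, bm, by, w)
  sum(w * abs(by - par[1] * bx - par[2] * bm))

## IRLS for weighted L1 regression through the origin with epsilon
## smoothing, polished by Nelder-Mead on the exact objective.
.l1_fit <- function(bx, bm, by, w, eps = 1e-8, max_iter = 200, tol = 1e-10) {
  A <- cbind(bx, bm)
  ww <- w
  coefs <- drop(solve(t(A * ww) %*% A, t(A * ww) %*% by))   # IVW start
  for (it in seq_len(max_iter)) {
    r <- by - drop(A %*% coefs)
    ww <- w / pmax(abs(r), eps)
    AtW <- t(A * ww)
    new <- tryCatch(drop(solve(AtW %*% A, AtW %*% by)), error = function(e) coefs)
    if (max(abs(new - coefs)) < tol) { coefs <- new; break }
    coefs <- new
  }
  pol <- stats::optim(coefs, .l1_objective, bx = bx, bm = bm, by = by, w = w,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  unname(if (pol$value <= .l1_objective(coefs, bx, bm, by, w)) pol$par
         else coefs)
}

#' Median-type multivariable MR (weighted L1 regression)
#'
#' Minimizes the weighted sum of absolute residuals
#' `sum(w_k |beta_out_k - delta*beta_x_k - beta*beta_m_k|)` with
#' `w_k = 1/se_out_k^2`, through the origin; robust to a minority of
#' pleiotropic instruments. Solved by iteratively reweighted least squares
#' with epsilon smoothing, polished by direct search on the exact
#' objective. The coefficient covariance is estimated by a parametric
#' bootstrap of the summary statistics.
#'
#' @inheritParams mvmr_ivw
#' @param se_x,se_m Optional standard errors for the exposure and mediator
#'   associations; when supplied the bootstrap perturbs those sides too.
#' @param n_boot Bootstrap replicates (>= 100).
#' @param seed Optional integer seed applied locally.
#' @return An `mvmr_fit` object (field `boot` holds the replicate draws).
#' @export
mvmr_median <- function(beta_x, beta_m, beta_out, se_out,
                        se_x = NULL, se_m = NULL,
                        n_boot = 1000, seed = NULL, snp_id = NULL,
                        conf_level = 0.95) {
  .check_mvmr(beta_x, beta_m, beta_out, se_out, 4L, "mvmr_median")
  if (n_boot < 100) stop("mvmr_median: n_boot must be >= 100")
  w <- 1 / se_out^2
  .rank_check(cbind(beta_x, beta_m) * sqrt(w), "mvmr_median")
  coefs <- .l1_fit(beta_x, beta_m, beta_out, w)
  if (!is.null(seed)) set.seed(seed)
  k <- length(beta_x)
  boot <- matrix(NA_real_, n_boot, 2)
  for (i in seq_len(n_boot)) {
    bx <- if (is.null(se_x)) beta_x else stats::rnorm(k, beta_x, se_x)
    bm <- if (is.null(se_m)) beta_m else stats::rnorm(k, beta_m, se_m)
    by <- stats::rnorm(k, beta_out, se_out)
    boot[i, ] <- .l1_fit(bx, bm, by, w)
  }
  covb <- stats::cov(boot)
  .new_mvmr_fit("MVMR-Median", coefs[1], coefs[2], covb, k, 1,
                snps = snp_id, se_out = se_out, conf_level = conf_level,
                extra = list(boot = boot))
}

## Fit an MVMR estimator by name on a harmonized table over a SNP set.
.mvmr_on <- function(data, snps, estimator, n_boot = 1000, seed = NULL) {
  d <- data[data$snp_id %in% snps, , drop = FALSE]
  if (!nrow(d)) stop("no SNPs available for MVMR fit")
  switch(estimator,
    ivw = mvmr_ivw(d$a_hat, d$b_hat, d$pi_hat, d$se_pi, snp_id = d$snp_id),
    egger = mvmr_egger(d$a_hat, d$b_hat, d$pi_hat, d$se_pi, snp_id = d$snp_id),
    median = mvmr_median(d$a_hat, d$b_hat, d$pi_hat, d$se_pi,
                         se_x = d$se_a, se_m = d$se_b,
                         n_boot = n_boot, seed = seed, snp_id = d$snp_id),
    stop("unknown estimator: ", estimator))
}
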