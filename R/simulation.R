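## Generative model for the simulation study: individual-level exposure,
## mediator and outcome data under configurable pleiotropy, reduced to
## per-SNP summary statistics by simple linear regression.

.scenario_table <- list(
  S1 = list(design = "two-sample", types = character(0), directional = FALSE),
  S2 = list(design = "two-sample", types = "a", directional = FALSE),
  S3 = list(design = "two-sample", types = "b", directional = FALSE),
  S4 = list(design = "two-sample", types = "c", directional = FALSE),
  S5 = list(design = "two-sample", types = c("a", "b", "c"), directional = FALSE),
  S6 = list(design = "three-sample", types = c("a", "b", "c"), directional = FALSE),
  S7 = list(design = "two-sample", types = "a", directional = TRUE),
  S8 = list(design = "two-sample", types = "b", directional = TRUE),
  S9 = list(design = "two-sample", types = "c", directional = TRUE),
  S10 = list(design = "two-sample", types = c("a", "b", "c"), directional = TRUE),
  S11 = list(design = "three-sample", types = c("a", "b", "c"), directional = TRUE))

#' Parameterize a simulation scenario
#'
#' Returns the complete parameterization of one of the eleven evaluation
#' scenarios: 80 exposure and 80 mediator SNPs per trait (the first 60 of
#' each mutually uncorrelated, the last 20 cross-correlated pairs at 0.5
#' with shared allele frequency), allele frequencies uniform on (0.3, 0.7),
#' per-SNP effects uniform on (0.02, 0.06), causal effects
#' (alpha, beta, delta) = (0.3, 0.3, 0.21) so the total effect is 0.3 and
#' the mediation proportion 0.3, trivariate-normal confounders, and a
#' scenario-specific pleiotropy pattern: 20 percent of SNPs per coefficient
#' family receive nonzero pleiotropic effects drawn uniformly from
#' (-0.03, 0.03) (balanced) or (-0.02, 0.04) (directional).
#'
#' Pleiotropy types: (a) exposure instruments affecting the mediator and
#' vice versa; (b) horizontal pleiotropy directly on the outcome; (c)
#' confounding pleiotropy through the shared confounders.
#'
#' Genotype dosages are standardized (mean 0, variance 1) before entering
#' the confounder and trait models, so each SNP's contribution to trait
#' variance is its squared coefficient regardless of allele frequency.
#'
#' @param scenario Scenario identifier, `"S1"` through `"S11"`.
#' @param n Individuals per sample (default 80000).
#' @param n_snps Instruments per trait (default 80).
#' @param n_uncorrelated Size of the uncorrelated subsets GX', GM'
#'   (default 60).
#' @param tail_corr Genotype correlation of the trailing exposure-mediator
#'   SNP pairs (default 0.5).
#' @param maf_range,effect_range,pleiotropy_fraction Ranges for allele
#'   frequencies and per-SNP effects, and the fraction of SNPs per family
#'   with nonzero pleiotropy.
#' @param alpha,beta,delta True causal effects.
#' @param standardize_genotypes Standardize dosages in the generative model
#'   (default `TRUE`).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = "S1", n = 80000, n_snps = 80,
                          n_uncorrelated = 60, tail_corr = 0.5,
                          maf_range = c(0.3, 0.7),
                          effect_range = c(0.02, 0.06),
                          pleiotropy_fraction = 0.2,
                          alpha = 0.3, beta = 0.3, delta = 0.21,
                          standardize_genotypes = TRUE) {
  scenario <- match.arg(scenario, names(.scenario_table))
  sc <- .scenario_table[[scenario]]
  stopifnot(n >= 2, n_snps >= n_uncorrelated, n_uncorrelated >= 1,
            tail_corr >= 0, tail_corr <= 1)
  structure(list(
    scenario = scenario, design = sc$design,
    pleiotropy_types = sc$types, directional = sc$directional,
    pleiotropy_range = if (sc$directional) c(-0.02, 0.04) else c(-0.03, 0.03),
    n = as.integer(n), n_snps = as.integer(n_snps),
    n_uncorrelated = as.integer(n_uncorrelated), tail_corr = tail_corr,
    maf_range = maf_range, effect_range = effect_range,
    pleiotropy_fraction = pleiotropy_fraction,
    alpha = alpha, beta = beta, delta = delta,
    gamma_x = c(1, 0, 1), gamma_m = c(1, 1, 0), gamma_y = c(0, 1, 1),
    confounder_cov = matrix(c(0.6, 0.2, 0.4,
                              0.2, 0.6, 0.2,
                              0.4, 0.2, 0.6), 3, 3),
    standardize_genotypes = standardize_genotypes),
    class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario %s: %s design, pleiotropy %s%s\n", x$scenario,
              x$design,
              if (length(x$pleiotropy_types))
                paste0("type (", paste(x$pleiotropy_types, collapse = ","), ")")
              else "none",
              if (length(x$pleiotropy_types))
                paste0(", ", if (x$directional) "directional" else "balanced")
              else ""))
  cat(sprintf("  n = %d per sample; %d + %d SNPs (%d + %d uncorrelated)\n",
              x$n, x$n_snps, x$n_snps, x$n_uncorrelated, x$n_uncorrelated))
  cat(sprintf("  true effects: alpha %.3g, beta %.3g, delta %.3g (TE %.3g, rho %.3g)\n",
              x$alpha, x$beta, x$delta, x$alpha * x$beta + x$delta,
              x$alpha * x$beta / (x$alpha * x$beta + x$delta)))
  invisible(x)
}

## Draw the per-replicate coefficient set (shared across samples).
.draw_coefficients <- function(spec) {
  K <- spec$n_snps; nu <- spec$n_uncorrelated
  runifr <- function(k, r) stats::runif(k, r[1], r[2])
  p_x <- runifr(K, spec$maf_range)
  p_m <- runifr(K, spec$maf_range)
  if (K > nu) p_m[(nu + 1):K] <- p_x[(nu + 1):K]  # paired SNPs share freq
  co <- list(
    p_x = p_x, p_m = p_m,
    a_x = runifr(K, spec$effect_range),    # GX -> X
    b_m = runifr(K, spec$effect_range),    # GM -> M
    a_m = numeric(K), b_x = numeric(K),    # type (a)
    c_x = numeric(K), c_m = numeric(K),    # type (b)
    d_x = matrix(0, 3, K), d_m = matrix(0, 3, K))  # type (c)
  n_pleio <- ceiling(spec$pleiotropy_fraction * K)
  draw <- function() {
    v <- numeric(K)
    idx <- sample.int(K, n_pleio)
    v[idx] <- runifr(n_pleio, spec$pleiotropy_range)
    v
  }
  if ("a" %in% spec$pleiotropy_types) {
    co$a_m <- draw()                       # GM SNPs affecting X
    co$b_x <- draw()                       # GX SNPs affecting M
  }
  if ("b" %in% spec$pleiotropy_types) {
    co$c_x <- draw()
    co$c_m <- draw()
  }
  if ("c" %in% spec$pleiotropy_types) {
    idx <- sample.int(K, n_pleio)
    for (j in 1:3) co$d_x[j, idx] <- runifr(n_pleio, spec$pleiotropy_range)
    idx <- sample.int(K, n_pleio)
    for (j in 1:3) co$d_m[j, idx] <- runifr(n_pleio, spec$pleiotropy_range)
  }
  co
}

## Genotypes for one sample: exposure and mediator panels with the trailing
## pairs correlated via a shared/independent allele-draw mixture (each of
## the two allele draws of a pair is the same Bernoulli outcome with
## probability tail_corr, independent otherwise, giving genotype
## correlation tail_corr with identical Binomial(2, p) marginals).
.gen_genotypes <- function(spec, co) {
  n <- spec$n; K <- spec$n_snps; nu <- spec$n_uncorrelated
  gx <- matrix(stats::rbinom(n * K, 2L, rep(co$p_x, each = n)), n, K)
  gm <- matrix(stats::rbinom(n * K, 2L, rep(co$p_m, each = n)), n, K)
  if (K > nu && spec$tail_corr > 0) {
    tail <- (nu + 1):K
    nt <- n * length(tail)
    p <- rep(co$p_x[tail], each = n)
    acc_x <- integer(nt); acc_m <- integer(nt)
    for (draw in 1:2) {
      base <- stats::rbinom(nt, 1L, p)
      indep <- stats::rbinom(nt, 1L, p)
      share <- stats::rbinom(nt, 1L, spec$tail_corr)
      acc_x <- acc_x + base
      acc_m <- acc_m + share * base + (1L - share) * indep
    }
    gx[, tail] <- acc_x
    gm[, tail] <- acc_m
  }
  storage.mode(gx) <- "double"; storage.mode(gm) <- "double"
  if (spec$standardize_genotypes) {
    # column-wise population standardization; loop avoids large temporaries
    mx <- 2 * co$p_x; sx <- sqrt(2 * co$p_x * (1 - co$p_x))
    mm <- 2 * co$p_m; sm <- sqrt(2 * co$p_m * (1 - co$p_m))
    for (k in seq_len(K)) {
      gx[, k] <- (gx[, k] - mx[k]) / sx[k]
      gm[, k] <- (gm[, k] - mm[k]) / sm[k]
    }
  }
  list(gx = gx, gm = gm)
}

#' Simulate one individual-level sample
#'
#' Generates genotypes, confounders and the exposure, mediator and outcome
#' traits for `spec$n` individuals under the given coefficient set.
#' Confounders are a trivariate normal plus (for confounding-pleiotropy
#' scenarios) genetic terms; traits follow the linear structural model with
#' standard-normal errors.
#'
#' @param spec A [scenario_spec()].
#' @param coefficients Coefficient set; drawn fresh when `NULL`. Mostly an
#'   internal argument: [generate_scenario()] draws one coefficient set and
#'   shares it across the samples of a replicate.
#' @return List with standardized genotype matrices `gx`, `gm` and trait
#'   vectors `x`, `m`, `y`, plus the coefficient set.
#' @export
simulate_individuals <- function(spec, coefficients = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  co <- if (is.null(coefficients)) .draw_coefficients(spec) else coefficients
  n <- spec$n
  g <- .gen_genotypes(spec, co)
  eps_u <- matrix(stats::rnorm(3 * n), n, 3) %*% chol(spec$confounder_cov)
  U <- eps_u + g$gx %*% t(co$d_x) + g$gm %*% t(co$d_m)
  x <- drop(U %*% spec$gamma_x) + stats::rnorm(n) +
    drop(g$gx %*% co$a_x) + drop(g$gm %*% co$a_m)
  m <- spec$alpha * x + drop(U %*% spec$gamma_m) + stats::rnorm(n) +
    drop(g$gm %*% co$b_m) + drop(g$gx %*% co$b_x)
  y <- spec$delta * x + spec$beta * m + drop(U %*% spec$gamma_y) +
    stats::rnorm(n) + drop(g$gx %*% co$c_x) + drop(g$gm %*% co$c_m)
  list(gx = g$gx, gm = g$gm, x = x, m = m, y = y, coefficients = co)
}

## Per-SNP simple linear regression of each trait in ys (a list of numeric
## vectors) on each column of G, sharing the genotype moments across traits.
.marginal_ols_multi <- function(G, ys) {
  n <- nrow(G)
  gbar <- colMeans(G)
  sxx <- colSums(G^2) - n * gbar^2
  if (any(sxx <= 0)) stop("monomorphic SNP: undefined regression SE")
  lapply(ys, function(y) {
    yc <- y - mean(y)
    sxy <- drop(crossprod(G, yc))          # centering G not needed against yc
    beta <- sxy / sxx
    s2 <- pmax(sum(yc^2) - beta * sxy, 0) / (n - 2)
    list(beta = beta, se = sqrt(s2 / sxx))
  })
}

.marginal_ols <- function(G, y) .marginal_ols_multi(G, list(y))[[1]]

#' Reduce individual-level samples to harmonized summary statistics
#'
#' Runs the per-SNP simple linear regressions of each trait on each of the
#' exposure and mediator instruments, using the sample appropriate to the
#' design: in the two-sample design the exposure and mediator associations
#' come from the first sample and the outcome associations from the second;
#' in the three-sample design each trait has its own sample.
#'
#' @param samples List of samples from [simulate_individuals()]: two
#'   (`xm`, `y`) or three (`x`, `m`, `y`) depending on the design.
#' @param design `"two-sample"` or `"three-sample"`.
#' @return A `harmonized_data` data frame (160 rows; SNP identifiers
#'   `GX01..GX80`, `GM01..GM80`).
#' @export
summarize_associations <- function(samples, design = c("two-sample",
                                                       "three-sample")) {
  design <- match.arg(design)
  if (design == "two-sample") {
    stopifnot(all(c("xm", "y") %in% names(samples)))
    K <- ncol(samples$xm$gx)
    xm_res <- .marginal_ols_multi(cbind(samples$xm$gx, samples$xm$gm),
                                  list(samples$xm$x, samples$xm$m))
    a <- xm_res[[1]]; b <- xm_res[[2]]
    pp <- .marginal_ols(cbind(samples$y$gx, samples$y$gm), samples$y$y)
  } else {
    stopifnot(all(c("x", "m", "y") %in% names(samples)))
    K <- ncol(samples$x$gx)
    a <- .marginal_ols(cbind(samples$x$gx, samples$x$gm), samples$x$x)
    b <- .marginal_ols(cbind(samples$m$gx, samples$m$gm), samples$m$m)
    pp <- .marginal_ols(cbind(samples$y$gx, samples$y$gm), samples$y$y)
  }
  ids <- c(sprintf("GX%02d", seq_len(K)), sprintf("GM%02d", seq_len(K)))
  out <- data.frame(snp_id = ids,
                    a_hat = a$beta, se_a = a$se,
                    b_hat = b$beta, se_b = b$se,
                    pi_hat = pp$beta, se_pi = pp$se,
                    stringsAsFactors = FALSE)
  class(out) <- c("harmonized_data", "data.frame")
  out
}

#' Generate one replicate of simulated summary data
#'
#' Draws a coefficient set for the scenario (genetic effects, allele
#' frequencies and pleiotropy pattern), simulates the individual-level
#' samples required by the design, and reduces them to per-SNP summary
#' statistics, together with instrument sets, the true effects and per-SNP
#' validity flags.
#'
#' @param spec A [scenario_spec()].
#' @param seed Optional integer seed applied before any draw.
#' @param keep_individuals Also return the individual-level samples (large;
#'   needed for [variance_explained()]).
#' @return List of class `sim_summary_data` with elements `data`
#'   (harmonized summary table), `sets` ([instrument_sets()]), `truth`
#'   (named list `te`, `de`, `ie`, `rho`, `alpha`, `beta`, `delta`),
#'   `valid` (logical vectors `gx`, `gm`), `coefficients`, `spec`, and
#'   optionally `individuals`.
#' @export
generate_scenario <- function(spec, seed = NULL, keep_individuals = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(seed)) set.seed(seed)
  co <- .draw_coefficients(spec)
  if (spec$design == "two-sample") {
    samples <- list(xm = simulate_individuals(spec, co),
                    y = simulate_individuals(spec, co))
  } else {
    samples <- list(x = simulate_individuals(spec, co),
                    m = simulate_individuals(spec, co),
                    y = simulate_individuals(spec, co))
  }
  data <- summarize_associations(samples, spec$design)
  K <- spec$n_snps; nu <- spec$n_uncorrelated
  sets <- instrument_sets(gx = sprintf("GX%02d", seq_len(K)),
                          gm = sprintf("GM%02d", seq_len(K)),
                          gx_prime = sprintf("GX%02d", seq_len(nu)),
                          gm_prime = sprintf("GM%02d", seq_len(nu)))
  te <- spec$alpha * spec$beta + spec$delta
  truth <- list(te = te, de = spec$delta, ie = spec$alpha * spec$beta,
                rho = spec$alpha * spec$beta / te,
                alpha = spec$alpha, beta = spec$beta, delta = spec$delta)
  valid <- list(
    gx = co$b_x == 0 & co$c_x == 0 & colSums(abs(co$d_x)) == 0,
    gm = co$a_m == 0 & co$c_m == 0 & colSums(abs(co$d_m)) == 0)
  out <- list(data = data, sets = sets, truth = truth, valid = valid,
              coefficients = co, spec = spec)
  if (keep_individuals) out$individuals <- samples
  structure(out, class = "sim_summary_data")
}

#' @export
print.sim_summary_data <- function(x, ...) {
  cat("Simulated summary data,", x$spec$scenario, "\n")
  cat(sprintf("  %d SNPs; valid instruments GX': %d/%d, GM': %d/%d\n",
              nrow(x$data),
              sum(x$valid$gx[seq_len(x$spec$n_uncorrelated)]),
              x$spec$n_uncorrelated,
              sum(x$valid$gm[seq_len(x$spec$n_uncorrelated)]),
              x$spec$n_uncorrelated))
  cat(sprintf("  truth: TE %.3g DE %.3g IE %.3g rho %.3g\n",
              x$truth$te, x$truth$de, x$truth$ie, x$truth$rho))
  invisible(x)
}

#' Variance of a trait explained jointly by a SNP set
#'
#' Multiple-regression R-squared of the trait on all genotype columns of
#' the set within one sample.
#'
#' @param genotypes Numeric matrix (individuals by SNPs).
#' @param trait Numeric trait vector.
#' @return R-squared (fraction in `[0, 1]`).
#' @export
variance_explained <- function(genotypes, trait) {
  stopifnot(nrow(genotypes) == length(trait), ncol(genotypes) >= 1)
  fit <- stats::.lm.fit(cbind(1, genotypes), trait)
  1 - sum(fit$residuals^2) / sum((trait - mean(trait))^2)
}

#' Mean conventional instrument F-statistic
#'
#' Averages the per-SNP squared t-ratios `(beta/se)^2` over a SNP set.
#'
#' @param beta,se Per-SNP association estimates and standard errors.
#' @return The mean F-statistic.
#' @export
mean_f_statistic <- function(beta, se) {
  stopifnot(length(beta) == length(se), length(beta) >= 1, all(se > 0))
  mean((beta / se)^2)
}

#' Two-sample conditional instrument-strength statistic (experimental)
#'
#' Measures how much instrument strength each trait retains conditional on
#' the other within the combined set: the exposure associations are
#' regressed on the mediator associations (inverse-variance weighted), and
#' the statistic is the weighted residual sum of squares standardized by
#' the first-order variance `se_a^2 + g^2 se_b^2`, divided by K - 1; and
#' symmetrically for the mediator. When the two association vectors are
#' unrelated it is close to the mean conventional F-statistic; when they
#' are proportional it collapses toward zero. The exact formula of the
#' published conditional F-statistic is not reproduced here; treat this as
#' a qualitative diagnostic.
#'
#' @param data A `harmonized_data` table.
#' @param sets An [instrument_sets()] object; the statistic is computed
#'   over `gx_prime U gm_prime`.
#' @return Named numeric vector `c(x = ..., m = ...)`.
#' @export
conditional_f_statistic <- function(data, sets) {
  snps <- union(sets$gx_prime, sets$gm_prime)
  d <- data[data$snp_id %in% snps, , drop = FALSE]
  cond <- function(a, se_a, b, se_b) {
    w <- 1 / se_a^2
    g <- sum(w * a * b) / sum(w * b^2)
    q <- sum((a - g * b)^2 / (se_a^2 + g^2 * se_b^2))
    q / (length(a) - 1)
  }
  c(x = cond(d$a_hat, d$se_a, d$b_hat, d$se_b),
    m = cond(d$b_hat, d$se_b, d$a_hat, d$se_a))
}
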