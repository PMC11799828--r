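test_that("cov_total_direct sums shared-SNP weight products", {
  # no shared SNPs -> exactly zero
  tf <- mr_ivw(c(1, 1), c(2, 2), c(1, 1), snp_id = c("s1", "s2"))
  df <- list(snps = c("s3", "s4"), weights_delta = c(0.5, 0.5), phi = 1,
             se_out = c(1, 1))
  expect_identical(cov_total_direct(tf, df), 0)

  # single shared SNP with unit weights: covariance 1, and Eq-7 style
  # Var(IE) = Var(TE) + Var(DE) - 2 Cov = 1 + 1 - 2 = 0 when both
  # estimators are the same single-instrument ratio
  tf1 <- mr_ivw(1, 0.4, 1, snp_id = "s1")     # weight c = 1, Var = 1
  df1 <- list(snps = "s1", weights_delta = 1, phi = 1, se_out = 1)
  cv <- cov_total_direct(tf1, df1)
  expect_equal(cv, 1)
  expect_equal(tf1$se^2 + 1 - 2 * cv, 0)

  # the covariance itself carries no heterogeneity inflation
  df2 <- list(snps = "s1", weights_delta = 1, phi = 4, se_out = 1)
  expect_equal(cov_total_direct(tf1, df2), 1)
  # partial overlap: only shared SNPs contribute
  tf2 <- mr_ivw(c(1, 1), c(0.4, 0.6), c(1, 1), snp_id = c("s1", "s2"))
  df4 <- list(snps = c("s2", "s3"), weights_delta = c(0.25, 0.75),
              phi = 1, se_out = c(2, 1))
  expect_equal(cov_total_direct(tf2, df4),
               unname(tf2$weights[2]) * 0.25 * 4)
})

test_that("reconstructed covariance matches a Monte-Carlo oracle", {
  # zero-heterogeneity fixture: observed outcome associations exactly on
  # the joint linear model, so the fits report phi = 1 and the claimed
  # covariance should match the empirical covariance of the two estimators
  # over regenerations of the outcome statistics
  set.seed(31)
  k_x <- 6; k_m <- 4
  a <- c(runif(k_x, 0.3, 1), rep(0, k_m))
  b <- c(0.4 * a[1:k_x], runif(k_m, 0.3, 1))
  se_pi <- runif(k_x + k_m, 0.05, 0.2)
  pi0 <- 0.25 * a + 0.5 * b
  ids <- sprintf("s%02d", seq_len(k_x + k_m))
  gx <- ids[1:k_x]

  n_mc <- 20000
  tau_hat <- delta_hat <- numeric(n_mc)
  for (i in seq_len(n_mc)) {
    pi_star <- rnorm(k_x + k_m, pi0, se_pi)
    tau_hat[i] <- mr_ivw(a[1:k_x], pi_star[1:k_x], se_pi[1:k_x])$estimate
    delta_hat[i] <- mvmr_ivw(a, b, pi_star, se_pi)$delta
  }
  emp_cov <- cov(tau_hat, delta_hat)

  tf <- mr_ivw(a[1:k_x], pi0[1:k_x], se_pi[1:k_x], snp_id = gx)
  mf <- mvmr_ivw(a, b, pi0, se_pi, snp_id = ids)
  expect_equal(tf$phi, 1)   # exact fit: no heterogeneity inflation
  expect_equal(mf$phi, 1)
  claimed <- cov_total_direct(tf, mf)

  mc_se <- sqrt((var(tau_hat) * var(delta_hat) + emp_cov^2) / (n_mc - 1))
  expect_lt(abs(claimed - emp_cov), 3 * mc_se)

  # same check for the Egger/MVMR-Egger pair
  tau_e <- delta_e <- numeric(n_mc)
  set.seed(32)
  for (i in seq_len(n_mc)) {
    pi_star <- rnorm(k_x + k_m, pi0, se_pi)
    tau_e[i] <- mr_egger(a[1:k_x], pi_star[1:k_x], se_pi[1:k_x])$estimate
    delta_e[i] <- mvmr_egger(a, b, pi_star, se_pi)$delta
  }
  tfe <- mr_egger(a[1:k_x], pi0[1:k_x], se_pi[1:k_x], snp_id = gx)
  mfe <- mvmr_egger(a, b, pi0, se_pi, snp_id = ids)
  claimed_e <- cov_total_direct(tfe, mfe)
  emp_cov_e <- cov(tau_e, delta_e)
  mc_se_e <- sqrt((var(tau_e) * var(delta_e) + emp_cov_e^2) / (n_mc - 1))
  expect_lt(abs(claimed_e - emp_cov_e), 3 * mc_se_e)
})

test_that("point estimates satisfy the mediation identities for all methods", {
  toy <- toy_mediation_data(seed = 33)
  # add mild noise so the fixture is not degenerate
  set.seed(34)
  d <- toy$data
  d$a_hat <- d$a_hat + rnorm(nrow(d), 0, 0.01)
  d$b_hat <- d$b_hat + rnorm(nrow(d), 0, 0.01)
  d$pi_hat <- d$pi_hat + rnorm(nrow(d), 0, 0.01)
  for (m in mediation_methods()) {
    fit <- mr_mediate(d, toy$sets, m, n_boot = 100, seed = 35)
    cf <- coef(fit)
    expect_equal(unname(cf["TE"] - cf["DE"]), unname(cf["IE"]),
                 tolerance = 1e-12, label = m)
    expect_equal(unname(cf["IE"] / cf["TE"]), unname(cf["rho"]),
                 tolerance = 1e-12, label = m)
    expect_equal(fit$estimates$parameter, c("TE", "DE", "IE", "rho"))
    expect_true(all(is.finite(fit$estimates$se)), label = m)
  }
})

test_that("legacy and covariance-aware difference methods agree as expected", {
  toy <- toy_mediation_data(seed = 36)
  set.seed(37)
  d <- toy$data
  d$pi_hat <- d$pi_hat + rnorm(nrow(d), 0, 0.02)
  f0 <- mr_mediate(d, toy$sets, "Diff-IVW0")
  f1 <- mr_mediate(d, toy$sets, "Diff-IVW")
  # same MVMR fit: identical DE estimate and SE
  e0 <- f0$estimates; e1 <- f1$estimates
  expect_equal(e0[e0$parameter == "DE", c("estimate", "se")],
               e1[e1$parameter == "DE", c("estimate", "se")])
  # GX = GX' here, so the IE point estimates coincide; only Var differs
  expect_equal(e0[e0$parameter == "IE", "estimate"],
               e1[e1$parameter == "IE", "estimate"])
  expect_identical(f0$cov_total_direct, 0)
  # positive covariance makes the legacy interval wider
  expect_gt(f1$cov_total_direct, 0)
  expect_gt(e0[e0$parameter == "IE", "se"], e1[e1$parameter == "IE", "se"])
})

test_that("product-method variances follow the delta-method composition", {
  toy <- toy_mediation_data(seed = 38)
  set.seed(39)
  d <- toy$data
  d$b_hat <- d$b_hat + rnorm(nrow(d), 0, 0.01)
  d$pi_hat <- d$pi_hat + rnorm(nrow(d), 0, 0.01)
  fit <- mr_mediate(d, toy$sets, "Prod-IVW")
  alpha <- fit$components$alpha$estimate
  v_a <- fit$components$alpha$se^2
  beta <- fit$components$beta$estimate
  v_b <- fit$components$beta$se^2
  te <- fit$components$total$estimate
  v_te <- fit$components$total$se^2
  e <- fit$estimates
  expect_equal(e[e$parameter == "IE", "se"]^2,
               alpha^2 * v_b + beta^2 * v_a, tolerance = 1e-12)
  expect_equal(e[e$parameter == "DE", "se"]^2,
               v_te + alpha^2 * v_b + beta^2 * v_a, tolerance = 1e-12)
  # rho variance agrees with numerical gradient propagation through
  # (alpha, beta, tau) -> alpha*beta/tau
  f <- function(p) p[1] * p[2] / p[3]
  p0 <- c(alpha, beta, te)
  h <- 1e-6
  g <- vapply(1:3, function(j) {
    e1 <- p0; e2 <- p0
    e1[j] <- e1[j] + h; e2[j] <- e2[j] - h
    (f(e1) - f(e2)) / (2 * h)
  }, numeric(1))
  v_num <- sum(g^2 * c(v_a, v_b, v_te))
  expect_equal(e[e$parameter == "rho", "se"]^2, v_num, tolerance = 1e-6)
})

test_that("difference-method rho variance matches numerical propagation", {
  toy <- toy_mediation_data(seed = 40)
  set.seed(40)
  d <- toy$data
  d$pi_hat <- d$pi_hat + rnorm(nrow(d), 0, 0.02)
  fit <- mr_mediate(d, toy$sets, "Diff-IVW")
  te <- fit$components$total$estimate; v_te <- fit$components$total$se^2
  de <- fit$components$direct$delta; v_de <- fit$components$direct$se_delta^2
  cv <- fit$cov_total_direct
  f <- function(p) 1 - p[2] / p[1]
  h <- 1e-6
  g <- vapply(1:2, function(j) {
    e1 <- c(te, de); e2 <- c(te, de)
    e1[j] <- e1[j] + h; e2[j] <- e2[j] - h
    (f(e1) - f(e2)) / (2 * h)
  }, numeric(1))
  S <- matrix(c(v_te, cv, cv, v_de), 2)
  v_num <- drop(t(g) %*% S %*% g)
  e <- fit$estimates
  expect_equal(e[e$parameter == "rho", "se"]^2, v_num, tolerance = 1e-6)
})

test_that("null mediation gives near-zero indirect effect", {
  # mediator-outcome path absent: pi unrelated to b on GM'
  set.seed(41)
  k <- 6
  a <- c(runif(k, 0.2, 0.5), rep(0, k))
  b <- c(0.4 * a[1:k], runif(k, 0.2, 0.5))
  pi <- 0.3 * a                      # delta = 0.3, beta = 0
  ids <- sprintf("s%02d", 1:(2 * k))
  d <- data.frame(snp_id = ids, a_hat = a + rnorm(2 * k, 0, 0.005),
                  se_a = 0.01, b_hat = b + rnorm(2 * k, 0, 0.005),
                  se_b = 0.01, pi_hat = pi + rnorm(2 * k, 0, 0.005),
                  se_pi = 0.01, stringsAsFactors = FALSE)
  sets <- instrument_sets(gx = ids[1:k], gm = ids[(k + 1):(2 * k)])
  fit <- mr_mediate(d, sets, "Prod-IVW")
  cf <- coef(fit)
  expect_lt(abs(cf["IE"]), 0.02)
  expect_equal(unname(cf["DE"]), unname(cf["TE"]), tolerance = 0.05)
})

test_that("parametric bootstrap is deterministic and collapses without noise", {
  toy <- toy_mediation_data(seed = 42, se = 1e-10)
  b1 <- parametric_bootstrap_ci(toy$data, toy$sets, "Diff-Median",
                                n_boot = 100, seed = 7)
  b2 <- parametric_bootstrap_ci(toy$data, toy$sets, "Diff-Median",
                                n_boot = 100, seed = 7)
  expect_identical(b1$replicates, b2$replicates)
  # zero-noise limit: intervals collapse onto the true values
  expect_lt(b1$ci["IE", 2] - b1$ci["IE", 1], 1e-6)
  expect_equal(unname(b1$ci["IE", 1]), toy$truth$ie, tolerance = 1e-4)
  expect_equal(unname(b1$ci["rho", 1]), toy$truth$rho, tolerance = 1e-4)

  toy2 <- toy_mediation_data(seed = 43, se = 0.03)
  f1 <- mr_mediate(toy2$data, toy2$sets, "Diff-Median", n_boot = 150, seed = 9)
  f2 <- mr_mediate(toy2$data, toy2$sets, "Diff-Median", n_boot = 150, seed = 9)
  expect_identical(f1$estimates, f2$estimates)
})

test_that("median-based methods recover a clean linear fixture", {
  toy <- toy_mediation_data(seed = 44, se = 0.02)
  fd <- mr_mediate(toy$data, toy$sets, "Diff-Median", n_boot = 150, seed = 10)
  fp <- mr_mediate(toy$data, toy$sets, "Prod-Median", n_boot = 150, seed = 10)
  for (fit in list(fd, fp)) {
    cf <- coef(fit)
    expect_equal(unname(cf["TE"]), toy$truth$te, tolerance = 1e-6)
    expect_equal(unname(cf["IE"]), toy$truth$ie, tolerance = 1e-6)
    expect_equal(unname(cf["rho"]), toy$truth$rho, tolerance = 1e-6)
  }
  # noiseless data: bootstrap intervals should cover the truth
  e <- fd$estimates
  expect_lte(e[e$parameter == "IE", "ci_low"], toy$truth$ie)
  expect_gte(e[e$parameter == "IE", "ci_high"], toy$truth$ie)
})

test_that("mediation results serialize to table and JSON", {
  toy <- toy_mediation_data(seed = 45, se = 0.02)
  fits <- mr_mediate_all(toy$data, toy$sets,
                         methods = c("Diff-IVW", "Prod-IVW"))
  tab <- mediation_table(fits)
  expect_equal(nrow(tab), 2L)
  expect_named(tab, c("method", "TE", "DE", "IE", "rho"))
  tab_or <- mediation_table(fits, exponentiate = TRUE)
  expect_false(identical(tab$TE, tab_or$TE))
  js <- jsonlite::fromJSON(mediation_json(fits))
  expect_equal(js$method, c("Diff-IVW", "Prod-IVW"))
})
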