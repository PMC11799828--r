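# Independent oracles and fixture builders used across the test files.
# Oracles deliberately use generic routines (lm / grid search / brute-force
# enumeration), never the package's own estimator code paths.

# Generic weighted least squares through lm(); returns coefficients and the
# unscaled coefficient covariance (sigma normalized out).
oracle_wls <- function(y, X, w, intercept = FALSE) {
  df <- as.data.frame(X)
  form <- if (intercept) stats::as.formula(paste("y ~", paste(names(df), collapse = "+")))
          else stats::as.formula(paste("y ~ 0 +", paste(names(df), collapse = "+")))
  df$y <- y
  fit <- stats::lm(form, data = df, weights = w)
  list(coef = stats::coef(fit),
       cov_unit = summary(fit)$cov.unscaled,
       rss = sum(w * stats::resid(fit)^2))
}

# Brute-force weighted median: scan the cumulative-weight breakpoints.
oracle_weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(x[1])
  if (0.5 >= s[length(s)]) return(x[length(x)])
  i <- max(which(s <= 0.5))
  x[i] + (0.5 - s[i]) / (s[i + 1] - s[i]) * (x[i + 1] - x[i])
}

# Grid search minimizer of the weighted L1 objective over (delta, beta).
oracle_l1_grid <- function(bx, bm, by, w, center, half_width = 0.5, steps = 81) {
  gd <- seq(center[1] - half_width, center[1] + half_width, length.out = steps)
  gb <- seq(center[2] - half_width, center[2] + half_width, length.out = steps)
  best <- c(NA, NA); best_val <- Inf
  for (d in gd) for (b in gb) {
    v <- sum(w * abs(by - d * bx - b * bm))
    if (v < best_val) { best_val <- v; best <- c(d, b) }
  }
  list(par = best, value = best_val)
}

# Brute-force connected components of a thresholded r2 graph.
oracle_components <- function(ids, R, threshold) {
  n <- length(ids)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && R[i, j] >= threshold && comp[j] != comp[i]) {
        comp[c(i, j)] <- min(comp[i], comp[j]); changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(ids, comp)
}

# Random small UVMR fixture.
random_uvmr_fixture <- function(k = 8) {
  list(bx = stats::runif(k, 0.2, 1) * sample(c(-1, 1), k, TRUE),
       by = stats::rnorm(k), se = stats::runif(k, 0.1, 0.5))
}

# Random small MVMR fixture.
random_mvmr_fixture <- function(k = 10) {
  list(bx = stats::rnorm(k), bm = stats::rnorm(k),
       by = stats::rnorm(k), se = stats::runif(k, 0.1, 0.5))
}

# Small harmonized table + sets with exact linear structure and known truth;
# noiseless unless SEs are used for perturbation.
toy_mediation_data <- function(k_x = 6, k_m = 6, alpha = 0.4, beta = 0.5,
                               delta = 0.2, se = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kk <- k_x + k_m
  a <- c(stats::runif(k_x, 0.1, 0.3), rep(0, k_m))
  b <- c(alpha * a[seq_len(k_x)], stats::runif(k_m, 0.1, 0.3))
  pi <- delta * a + beta * b
  ids <- sprintf("snp%02d", seq_len(kk))
  data <- data.frame(snp_id = ids, a_hat = a, se_a = se, b_hat = b,
                     se_b = se, pi_hat = pi, se_pi = se,
                     stringsAsFactors = FALSE)
  class(data) <- c("harmonized_data", "data.frame")
  sets <- instrument_sets(gx = ids[seq_len(k_x)], gm = ids[k_x + seq_len(k_m)])
  list(data = data, sets = sets,
       truth = list(te = alpha * beta + delta, de = delta,
                    ie = alpha * beta, rho = alpha * beta / (alpha * beta + delta)))
}

# Write a small GWAS summary table to a temp file; returns the path.
write_gwas_fixture <- function(df, sep = "\t") {
  path <- tempfile(fileext = if (sep == "\t") ".tsv" else ".csv")
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
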