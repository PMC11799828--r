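test_that("read_gwas_table reads well-formed tables and applies column maps", {
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"), effect_allele = "A",
                   other_allele = "G", beta = c(0.1, -0.2, 0.3),
                   se = c(0.01, 0.02, 0.03), pval = c(1e-8, 1e-6, 1e-7))
  tab <- read_gwas_table(write_gwas_fixture(df))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$beta, df$beta)
  expect_equal(attr(tab, "n_dropped"), 0L)

  # comma-separated with renamed columns
  df2 <- data.frame(rsid = "rs9", ea = "C", oa = "T", b = 0.5, stderr = 0.1,
                    p = 0.01)
  tab2 <- read_gwas_table(write_gwas_fixture(df2, sep = ","),
                          column_map = c(snp_id = "rsid", effect_allele = "ea",
                                         other_allele = "oa", beta = "b",
                                         se = "stderr", pval = "p"))
  expect_equal(tab2$snp_id, "rs9")
  expect_equal(tab2$se, 0.1)
})

test_that("read_gwas_table drops invalid rows and errors on bad inputs", {
  df <- data.frame(SNP = c("rs1", "rs2"), effect_allele = "A",
                   other_allele = "G", beta = c(0.1, 0.2), se = c(0, 0.02),
                   pval = 0.5)
  expect_message(tab <- read_gwas_table(write_gwas_fixture(df)), "1 row")
  expect_equal(nrow(tab), 1L)
  expect_equal(attr(tab, "n_dropped"), 1L)

  # missing mapped beta column is a configuration error
  df3 <- data.frame(SNP = "rs1", effect_allele = "A", other_allele = "G",
                    se = 0.1, pval = 0.5)
  expect_error(read_gwas_table(write_gwas_fixture(df3)), "beta")
  # all rows invalid -> input error
  df4 <- data.frame(SNP = "rs1", effect_allele = "A", other_allele = "G",
                    beta = 0.1, se = -1, pval = 0.5)
  expect_error(suppressMessages(read_gwas_table(write_gwas_fixture(df4))),
               "no usable rows")
})

make_assoc <- function(ids, ea, oa, beta, eaf = NA_real_) {
  data.frame(snp_id = ids, effect_allele = ea, other_allele = oa,
             beta = beta, se = 0.05, pval = 1e-6, eaf = eaf,
             stringsAsFactors = FALSE)
}

test_that("harmonize aligns effects to the exposure effect allele", {
  ids <- c("rs1", "rs2", "rs3")
  sets <- instrument_sets(gx = c("rs1", "rs2"), gm = "rs3")
  x <- make_assoc(ids, c("A", "A", "A"), c("G", "G", "G"), c(0.1, 0.2, 0.3))
  m <- make_assoc(ids, c("A", "G", "A"), c("G", "A", "G"), c(0.4, 0.5, 0.6))
  y <- make_assoc(ids, c("A", "A", "G"), c("G", "G", "A"), c(0.7, 0.8, 0.9))
  h <- harmonize(x, m, y, sets)
  expect_equal(h$snp_id, ids)
  expect_equal(h$a_hat, c(0.1, 0.2, 0.3))       # exposure unchanged
  expect_equal(h$b_hat, c(0.4, -0.5, 0.6))      # rs2 swapped in mediator
  expect_equal(h$pi_hat, c(0.7, 0.8, -0.9))     # rs3 swapped in outcome
  expect_equal(h$source, c("GX'", "GX'", "GM'"))
})

test_that("harmonize drops irreconcilable or absent SNPs with reasons", {
  ids <- c("rs1", "rs2")
  sets <- instrument_sets(gx = ids, gm = character(0))
  x <- make_assoc(ids, c("A", "A"), c("G", "G"), c(0.1, 0.2))
  m <- make_assoc(ids, c("A", "A"), c("G", "C"), c(0.4, 0.5))  # rs2 A/C vs A/G
  y <- make_assoc(ids, c("A", "A"), c("G", "G"), c(0.7, 0.8))
  expect_message(h <- harmonize(x, m, y, sets), "dropped")
  expect_equal(h$snp_id, "rs1")
  dropped <- attr(h, "dropped")
  expect_equal(dropped$snp_id, "rs2")
  expect_match(dropped$reason, "allele mismatch")

  # SNP absent from the outcome table
  y2 <- y[1, ]
  expect_message(h2 <- harmonize(x, m[1, ], y2, instrument_sets(ids, character(0))),
                 "dropped")
  expect_match(attr(h2, "dropped")$reason, "absent")

  # everything dropped -> input error
  m3 <- make_assoc(ids, c("A", "A"), c("C", "C"), c(1, 1))
  expect_error(suppressMessages(harmonize(x, m3, y, sets)), "all instruments")
})

test_that("harmonization is involutive under sign-flip of an input table", {
  ids <- sprintf("rs%d", 1:4)
  sets <- instrument_sets(gx = ids[1:2], gm = ids[3:4])
  x <- make_assoc(ids, "A", "G", c(0.1, 0.2, 0.3, 0.4))
  m <- make_assoc(ids, "A", "G", c(0.5, 0.6, 0.7, 0.8))
  y <- make_assoc(ids, "A", "G", c(0.9, 1.0, 1.1, 1.2))
  h1 <- harmonize(x, m, y, sets)
  # flip the outcome table's alleles and beta signs: same harmonized result
  y2 <- y
  y2$effect_allele <- "G"; y2$other_allele <- "A"; y2$beta <- -y$beta
  h2 <- harmonize(x, m, y2, sets)
  expect_equal(h1, h2, ignore_attr = TRUE)
})

test_that("palindromic SNPs use frequency orientation or are dropped", {
  ids <- c("rs1", "rs2")
  sets <- instrument_sets(gx = ids, gm = character(0))
  # rs1: palindromic A/T, clear frequencies on the same side -> kept, aligned
  # rs2: palindromic, no eaf -> dropped
  x <- make_assoc(ids, c("A", "C"), c("T", "G"), c(0.1, 0.2),
                  eaf = c(0.2, NA))
  m <- make_assoc(ids, c("A", "C"), c("T", "G"), c(0.3, 0.4),
                  eaf = c(0.25, NA))
  y <- make_assoc(ids, c("A", "C"), c("T", "G"), c(0.5, 0.6),
                  eaf = c(0.22, NA))
  expect_message(h <- harmonize(x, m, y, sets))
  expect_equal(h$snp_id, "rs1")
  expect_equal(h$b_hat, 0.3)
  expect_match(attr(h, "dropped")$reason, "palindromic")

  # opposite-side frequencies flip the sign
  m2 <- m; m2$eaf <- c(0.78, NA); m2$beta <- c(-0.3, 0.4)
  expect_message(h2 <- harmonize(x, m2, y, sets))
  expect_equal(h2$b_hat, 0.3)
})

test_that("double_clump keeps the most significant SNP per LD block", {
  gx <- data.frame(snp_id = "rsX", pval = 1e-12)
  gm <- data.frame(snp_id = "rsM", pval = 1e-6)
  ld <- data.frame(snp1 = "rsX", snp2 = "rsM", r2 = 0.8)
  out <- double_clump(gx, gm, ld, r2_threshold = 0.1)
  expect_equal(out$gx_prime, "rsX")
  expect_equal(out$gm_prime, character(0))
  expect_equal(attr(out, "removed"), "rsM")

  # all r2 = 0: identity
  gx2 <- data.frame(snp_id = c("a1", "a2"), pval = c(1e-8, 1e-9))
  gm2 <- data.frame(snp_id = "b1", pval = 1e-7)
  ld0 <- expand.grid(snp1 = c("a1", "a2", "b1"), snp2 = c("a1", "a2", "b1"),
                     stringsAsFactors = FALSE)
  ld0 <- ld0[ld0$snp1 != ld0$snp2, ]; ld0$r2 <- 0
  out2 <- double_clump(gx2, gm2, ld0, r2_threshold = 0.1)
  expect_equal(out2$gx_prime, c("a1", "a2"))
  expect_equal(out2$gm_prime, "b1")
})

test_that("double_clump matches a brute-force component oracle on chains", {
  # chain a1 - b1 - a2: one survivor for the whole block
  ids <- c("a1", "a2", "b1")
  R <- diag(3); dimnames(R) <- list(ids, ids)
  R["a1", "b1"] <- R["b1", "a1"] <- 0.5
  R["a2", "b1"] <- R["b1", "a2"] <- 0.5   # a1-a2 not directly linked
  gx <- data.frame(snp_id = c("a1", "a2"), pval = c(1e-10, 1e-4))
  gm <- data.frame(snp_id = "b1", pval = 1e-6)
  out <- double_clump(gx, gm, R, r2_threshold = 0.1)
  comps <- oracle_components(ids, R, 0.1)
  expect_length(comps, 1L)                        # oracle agrees: one block
  survivors <- c(out$gx_prime, out$gm_prime)
  expect_length(survivors, 1L)
  expect_equal(survivors, "a1")                   # smallest p in the block

  # random fixtures: survivors are per-component p-value minima, removed
  # SNPs are in LD with some survivor
  set.seed(41)
  for (rep in 1:10) {
    n <- 8
    ids <- sprintf("s%d", 1:n)
    R <- diag(n); dimnames(R) <- list(ids, ids)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      r <- ifelse(runif(1) < 0.3, runif(1, 0.2, 1), 0)
      R[i, j] <- R[j, i] <- r
    }
    pv <- runif(n)
    gx <- data.frame(snp_id = ids[1:4], pval = pv[1:4])
    gm <- data.frame(snp_id = ids[5:8], pval = pv[5:8])
    out <- double_clump(gx, gm, R, r2_threshold = 0.2)
    survivors <- c(out$gx_prime, out$gm_prime)
    comps <- oracle_components(ids, R, 0.2)
    expect_length(survivors, length(comps))
    for (comp in comps) {
      surv <- intersect(survivors, comp)
      expect_length(surv, 1L)
      expect_equal(pv[match(surv, ids)], min(pv[match(comp, ids)]))
    }
    # every removed SNP sits in the component of exactly one survivor
    for (rem in setdiff(ids, survivors)) {
      comp <- comps[[which(vapply(comps, function(cc) rem %in% cc, logical(1)))]]
      expect_length(intersect(comp, survivors), 1L)
    }
    expect_length(intersect(out$gx_prime, out$gm_prime), 0L)
  }
})

test_that("double_clump refuses missing LD entries", {
  gx <- data.frame(snp_id = "a1", pval = 1e-8)
  gm <- data.frame(snp_id = "b1", pval = 1e-6)
  ld <- data.frame(snp1 = character(), snp2 = character(), r2 = numeric())
  expect_error(double_clump(gx, gm, ld, 0.1), "missing LD entry")
})

test_that("instrument_sets validates subset and disjointness invariants", {
  expect_error(instrument_sets(gx = "a", gm = "b", gx_prime = "c"), "subset")
  expect_error(instrument_sets(gx = c("a", "s"), gm = c("b", "s"),
                               gx_prime = "s", gm_prime = "s"), "disjoint")
})
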