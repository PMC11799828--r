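## Reading, validating and harmonizing GWAS summary statistics.

.default_columns <- c(snp_id = "SNP", effect_allele = "effect_allele",
                      other_allele = "other_allele", beta = "beta",
                      se = "se", pval = "pval", eaf = "eaf")

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file of per-SNP association results and returns a
#' validated data frame with standardized column names. Rows with missing
#' effect estimates or non-positive standard errors are dropped; the number
#' of dropped rows is reported via a message and attached as an attribute.
#'
#' @param path Path to a tab- or comma-separated text file. The delimiter is
#'   sniffed from the header line unless `sep` is given.
#' @param column_map Named character vector mapping the standardized names
#'   `snp_id`, `effect_allele`, `other_allele`, `beta`, `se`, `pval` and
#'   optionally `eaf` to the column names used in the file. Entries missing
#'   from the map fall back to the defaults
#'   `SNP, effect_allele, other_allele, beta, se, pval, eaf`.
#' @param sep Field separator; `NULL` (default) autodetects tab vs comma.
#' @return A data frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval` and (if present in the file)
#'   `eaf`, one row per retained variant, with attribute `n_dropped`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\teffect_allele\tother_allele\tbeta\tse\tpval",
#'              "rs1\tA\tG\t0.1\t0.01\t1e-8"), tf)
#' read_gwas_table(tf)
#' @export
read_gwas_table <- function(path, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  cmap <- .default_columns
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(cmap))
    if (length(bad))
      stop("unknown column_map entries: ", paste(bad, collapse = ", "))
    cmap[names(column_map)] <- column_map
  }
  required <- setdiff(names(cmap), "eaf")
  missing_cols <- required[!cmap[required] %in% names(raw)]
  if (length(missing_cols))
    stop("required column(s) not found in ", path, ": ",
         paste(sprintf("%s (mapped to '%s')", missing_cols, cmap[missing_cols]),
               collapse = ", "))
  out <- data.frame(
    snp_id = as.character(raw[[cmap["snp_id"]]]),
    effect_allele = toupper(as.character(raw[[cmap["effect_allele"]]])),
    other_allele = toupper(as.character(raw[[cmap["other_allele"]]])),
    beta = as.numeric(raw[[cmap["beta"]]]),
    se = as.numeric(raw[[cmap["se"]]]),
    pval = as.numeric(raw[[cmap["pval"]]]),
    stringsAsFactors = FALSE)
  out$eaf <- if (cmap["eaf"] %in% names(raw)) as.numeric(raw[[cmap["eaf"]]]) else NA_real_
  keep <- !is.na(out$beta) & !is.na(out$se) & out$se > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " row(s) dropped (missing beta or se <= 0) from ", path)
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no usable rows in ", path)
  bad_p <- !is.na(out$pval) & (out$pval < 0 | out$pval > 1)
  if (any(bad_p)) stop("p-values outside [0, 1] in ", path)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read an instrument list (one SNP identifier per line)
#'
#' @param path Path to a text file with one variant identifier per line;
#'   blank lines and lines starting with `#` are ignored.
#' @return Character vector of identifiers.
#' @export
read_instrument_list <- function(path) {
  if (!file.exists(path)) stop("instrument list not found: ", path)
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (!length(x)) stop("empty instrument list: ", path)
  unique(x)
}

#' Read pairwise LD as a three-column pair list
#'
#' @param path Text file with columns `snp1`, `snp2`, `r2` (tab or comma
#'   separated, header required).
#' @return Data frame with columns `snp1`, `snp2`, `r2`.
#' @export
read_ld_pairs <- function(path) {
  if (!file.exists(path)) stop("LD file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  ld <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("snp1", "snp2", "r2")
  if (!all(need %in% names(ld)))
    stop("LD file must have columns snp1, snp2, r2")
  ld$r2 <- as.numeric(ld$r2)
  if (any(is.na(ld$r2) | ld$r2 < 0 | ld$r2 > 1)) stop("r2 values must lie in [0, 1]")
  ld[need]
}

#' Bundle instrument sets for exposure and mediator
#'
#' @param gx,gm Character vectors of instrument identifiers for the exposure
#'   and the mediator.
#' @param gx_prime,gm_prime Mutually uncorrelated subsets (e.g., the output
#'   of [double_clump()]); default to `gx` and `gm`.
#' @return An object of class `instrument_sets`.
#' @export
instrument_sets <- function(gx, gm, gx_prime = gx, gm_prime = gm) {
  gx <- unique(as.character(gx)); gm <- unique(as.character(gm))
  gx_prime <- unique(as.character(gx_prime)); gm_prime <- unique(as.character(gm_prime))
  if (!all(gx_prime %in% gx)) stop("gx_prime must be a subset of gx")
  if (!all(gm_prime %in% gm)) stop("gm_prime must be a subset of gm")
  both <- intersect(gx_prime, gm_prime)
  if (length(both))
    stop("gx_prime and gm_prime must be disjoint; shared: ",
         paste(utils::head(both, 5L), collapse = ", "))
  structure(list(gx = gx, gm = gm, gx_prime = gx_prime, gm_prime = gm_prime),
            class = "instrument_sets")
}

#' @export
print.instrument_sets <- function(x, ...) {
  cat("Instrument sets:\n",
      sprintf("  GX : %d SNPs (GX' : %d)\n", length(x$gx), length(x$gx_prime)),
      sprintf("  GM : %d SNPs (GM' : %d)\n", length(x$gm), length(x$gm_prime)),
      sep = "")
  invisible(x)
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(a1, a2) {
  !is.na(.complement[a1]) & .complement[a1] == a2
}

## Align one table's (beta, eaf) to the reference alleles.
## Returns list(flip = -1/1/NA, reason) per row; NA flip means drop.
.align_alleles <- function(ref_ea, ref_oa, ea, oa, ref_eaf, eaf,
                           palindromic_eaf_limit = 0.42) {
  n <- length(ref_ea)
  flip <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  pal <- .is_palindromic(ref_ea, ref_oa)
  same <- ea == ref_ea & oa == ref_oa
  swap <- ea == ref_oa & oa == ref_ea
  cea <- unname(.complement[ea]); coa <- unname(.complement[oa])
  csame <- !is.na(cea) & !is.na(coa) & cea == ref_ea & coa == ref_oa
  cswap <- !is.na(cea) & !is.na(coa) & cea == ref_oa & coa == ref_ea
  for (i in seq_len(n)) {
    if (pal[i]) {
      if (!(same[i] || swap[i])) { reason[i] <- "allele mismatch"; next }
      if (is.na(ref_eaf[i]) || is.na(eaf[i])) {
        reason[i] <- "palindromic, eaf missing"; next
      }
      maf <- min(ref_eaf[i], 1 - ref_eaf[i], eaf[i], 1 - eaf[i])
      if (maf >= palindromic_eaf_limit) {
        reason[i] <- "palindromic, eaf ambiguous"; next
      }
      # orient by which side of 0.5 the frequencies fall on
      flip[i] <- if ((ref_eaf[i] < 0.5) == (eaf[i] < 0.5)) 1 else -1
    } else if (same[i] || csame[i]) {
      flip[i] <- 1
    } else if (swap[i] || cswap[i]) {
      flip[i] <- -1
    } else {
      reason[i] <- "allele mismatch"
    }
  }
  list(flip = flip, reason = reason)
}

#' Harmonize exposure, mediator and outcome summary statistics
#'
#' Aligns the per-SNP associations of the three traits to a common effect
#' allele (the exposure table's), producing one row per instrument with the
#' SNP-exposure, SNP-mediator and SNP-outcome estimates and standard errors.
#' Strand flips are resolved by complementing alleles; palindromic (A/T, C/G)
#' variants are oriented by effect-allele frequency when available in both
#' tables and unambiguous (minor-allele frequency below
#' `palindromic_eaf_limit`), otherwise dropped. Variants with irreconcilable
#' alleles, or absent from a required table, are dropped with a reason.
#'
#' @param x_assoc,m_assoc,y_assoc Data frames as returned by
#'   [read_gwas_table()] for the exposure, mediator and outcome.
#' @param sets An [instrument_sets()] object; all SNPs in `gx` and `gm` are
#'   harmonized (each must be present in all three tables).
#' @param palindromic_eaf_limit Palindromic variants are kept only when the
#'   minor-allele frequency in both tables is below this value (default 0.42).
#' @return A data frame of class `harmonized_data` with columns `snp_id`,
#'   `a_hat`, `se_a` (exposure), `b_hat`, `se_b` (mediator), `pi_hat`,
#'   `se_pi` (outcome) and `source` (one of `"GX'"`, `"GM'"`, `"GX-only"`,
#'   `"GM-only"`), sorted by `snp_id`. Dropped variants are reported in
#'   attribute `dropped` (data frame of `snp_id`, `reason`).
#' @export
harmonize <- function(x_assoc, m_assoc, y_assoc, sets,
                      palindromic_eaf_limit = 0.42) {
  stopifnot(inherits(sets, "instrument_sets"))
  wanted <- sort(union(sets$gx, sets$gm))
  dropped <- list()
  drop_snp <- function(id, why) dropped[[length(dropped) + 1L]] <<-
    data.frame(snp_id = id, reason = why, stringsAsFactors = FALSE)

  idx <- function(tab, label) {
    i <- match(wanted, tab$snp_id)
    i
  }
  ix <- match(wanted, x_assoc$snp_id)
  im <- match(wanted, m_assoc$snp_id)
  iy <- match(wanted, y_assoc$snp_id)
  present <- !is.na(ix) & !is.na(im) & !is.na(iy)
  for (j in which(!present)) {
    miss <- c("exposure", "mediator", "outcome")[c(is.na(ix[j]), is.na(im[j]), is.na(iy[j]))]
    drop_snp(wanted[j], paste("absent from", paste(miss, collapse = "+"), "table"))
  }
  keep <- which(present)
  if (!length(keep)) stop("no instrument present in all three tables")

  xs <- x_assoc[ix[keep], ]; ms <- m_assoc[im[keep], ]; ys <- y_assoc[iy[keep], ]
  am <- .align_alleles(xs$effect_allele, xs$other_allele,
                       ms$effect_allele, ms$other_allele,
                       xs$eaf, ms$eaf, palindromic_eaf_limit)
  ay <- .align_alleles(xs$effect_allele, xs$other_allele,
                       ys$effect_allele, ys$other_allele,
                       xs$eaf, ys$eaf, palindromic_eaf_limit)
  ok <- !is.na(am$flip) & !is.na(ay$flip)
  for (j in which(!ok)) {
    why <- if (!is.na(am$reason[j])) paste0("mediator: ", am$reason[j])
           else paste0("outcome: ", ay$reason[j])
    drop_snp(xs$snp_id[j], why)
  }
  if (!any(ok)) stop("all instruments dropped during harmonization")

  xs <- xs[ok, ]; ms <- ms[ok, ]; ys <- ys[ok, ]
  fm <- am$flip[ok]; fy <- ay$flip[ok]
  src <- ifelse(xs$snp_id %in% sets$gx_prime, "GX'",
         ifelse(xs$snp_id %in% sets$gm_prime, "GM'",
         ifelse(xs$snp_id %in% sets$gx, "GX-only", "GM-only")))
  out <- data.frame(
    snp_id = xs$snp_id,
    a_hat = xs$beta, se_a = xs$se,
    b_hat = fm * ms$beta, se_b = ms$se,
    pi_hat = fy * ys$beta, se_pi = ys$se,
    source = src,
    stringsAsFactors = FALSE)
  out <- out[order(out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("harmonized_data", "data.frame")
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped)
    else data.frame(snp_id = character(), reason = character())
  if (nrow(attr(out, "dropped")))
    message(nrow(attr(out, "dropped")), " instrument(s) dropped during harmonization")
  out
}

#' Write a harmonized table as TSV
#'
#' @param data A `harmonized_data` data frame from [harmonize()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(data, path) {
  utils::write.table(as.data.frame(data), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Double clumping of two instrument sets against precomputed LD
#'
#' Re-prunes the union of the exposure and mediator instrument sets so the
#' returned subsets are mutually uncorrelated. Variants are grouped into LD
#' blocks as connected components of the graph whose edges join pairs with
#' r-squared at or above `r2_threshold`; within each block only the variant
#' with the smallest p-value survives (ties broken by identifier order).
#'
#' LD must be supplied for every unordered pair of the union, either as a
#' pair list (`snp1`, `snp2`, `r2`) or as a named square matrix; a missing
#' pair is an error rather than being silently treated as independence.
#'
#' @param gx,gm Data frames with columns `snp_id` and `pval` listing the
#'   exposure and mediator instruments (disjoint).
#' @param ld Pair-list data frame (`snp1`, `snp2`, `r2`) or a symmetric
#'   numeric matrix with dimnames covering all instruments.
#' @param r2_threshold LD blocks are formed at `r2 >= r2_threshold`
#'   (0 < threshold < 1).
#' @return An [instrument_sets()] object with `gx_prime`/`gm_prime` the
#'   surviving subsets; the removed variants are recorded in attribute
#'   `removed`.
#' @export
double_clump <- function(gx, gm, ld, r2_threshold) {
  stopifnot(is.data.frame(gx), is.data.frame(gm),
            all(c("snp_id", "pval") %in% names(gx)),
            all(c("snp_id", "pval") %in% names(gm)))
  if (!(r2_threshold > 0 && r2_threshold < 1))
    stop("r2_threshold must lie strictly between 0 and 1")
  if (length(intersect(gx$snp_id, gm$snp_id)))
    stop("gx and gm must be disjoint instrument lists")
  ids <- c(gx$snp_id, gm$snp_id)
  pv <- c(gx$pval, gm$pval)
  n <- length(ids)

  R <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(R) <- 1
  if (is.matrix(ld)) {
    miss <- setdiff(ids, rownames(ld))
    if (length(miss)) stop("LD matrix lacks entries for: ",
                           paste(utils::head(miss, 5L), collapse = ", "))
    R[,] <- ld[ids, ids]
    diag(R) <- 1
  } else {
    k1 <- match(ld$snp1, ids); k2 <- match(ld$snp2, ids)
    okp <- !is.na(k1) & !is.na(k2)
    R[cbind(k1[okp], k2[okp])] <- ld$r2[okp]
    R[cbind(k2[okp], k1[okp])] <- ld$r2[okp]
    if (any(is.na(R))) {
      bad <- which(is.na(R), arr.ind = TRUE)[1, ]
      stop("missing LD entry for pair (", ids[bad[1]], ", ", ids[bad[2]],
           "); supply r2 for every pair of the union")
    }
  }

  adj <- R >= r2_threshold
  comp <- integer(n); comp[] <- 0L; cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i]) next
    cur <- cur + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (comp[v]) next
      comp[v] <- cur
      nb <- which(adj[v, ] & comp == 0L)
      stack <- c(stack, nb)
    }
  }
  ord <- order(comp, pv, ids)   # per component: smallest p, then id
  first <- !duplicated(comp[ord])
  survivors <- ids[ord][first]
  removed <- setdiff(ids, survivors)
  out <- instrument_sets(gx$snp_id, gm$snp_id,
                         intersect(gx$snp_id, survivors),
                         intersect(gm$snp_id, survivors))
  attr(out, "removed") <- removed
  out
}
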