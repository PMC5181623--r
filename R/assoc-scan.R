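#' Single SNP-site association (simple linear regression on dosage)
#'
#' OLS of the (residualized) methylation value on allele dosage: slope,
#' standard error, Wald t with n-2 df, two-sided p, and `r2` = squared
#' Pearson correlation.  Missing dosages are dropped pairwise.
#'
#' @param y phenotype vector (residual M-values).
#' @param g dosage vector (0/1/2/NA), same length.
#' @return list `beta, se, t, p, r2, n`; `NULL` (no-test sentinel) when
#'   fewer than 3 complete pairs remain or `g` is monomorphic among them.
#' @export
snp_assoc <- function(y, g) {
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  n <- length(y)
  if (n < 3 || var(g) == 0) return(NULL)
  gc <- g - mean(g); yc <- y - mean(y)
  ssx <- sum(gc^2)
  beta <- sum(gc * yc) / ssx
  res <- yc - beta * gc
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / ssx)
  t <- beta / se
  p <- 2 * pt(-abs(t), df = n - 2)
  r2 <- if (sum(yc^2) == 0) 1 else sum(gc * yc)^2 / (ssx * sum(yc^2))
  list(beta = beta, se = se, t = t, p = p, r2 = r2, n = n)
}

#' Expected number of significant tests under independence
#'
#' `n_tests * threshold`: the expected count of p-values below the
#' threshold when every test is null and tests are treated as independent
#' (LD-induced dependence is deliberately ignored, as in the accounting
#' this mirrors).
#'
#' @param n_tests number of tests performed.
#' @param threshold significance threshold.
#' @return expected count.
#' @export
expected_count <- function(n_tests, threshold) {
  stopifnot(n_tests >= 0)
  n_tests * threshold
}

#' SNP-by-SNP methylation QTL scan with cis/trans accounting
#'
#' Tests every SNP against every site with [snp_assoc()], classifies each
#' pair as `cis` (same chromosome and `|distance| <= cis_window`) or
#' `trans`, and tabulates, per threshold and relation, the observed count,
#' the expected count under independence, and the number of sites with at
#' least one significant association.  SNPs with minor allele count below
#' `mac_min` among complete pairs are skipped and excluded from the test
#' totals.
#'
#' @param resid_meth a [methylation_data()] of residualized M-values.
#' @param geno a [genotype_data()], samples aligned.
#' @param thresholds significance thresholds (default `c(5e-2, 5e-4, 5e-8)`).
#' @param cis_window cis half-width in bp (1e6; the boundary is cis).
#' @param mac_min minimum minor allele count (3).
#' @return list of class `gwas_scan`: `assoc` (data.frame per tested pair:
#'   `snp_id, site_id, beta, se, t, p, r2, relation, distance`), `summary`
#'   (per threshold x relation: `count, count_expected, count_sites`), and
#'   `n_tests` (named: cis, trans).
#' @export
gwas_scan <- function(resid_meth, geno, thresholds = c(5e-2, 5e-4, 5e-8),
                      cis_window = 1e6, mac_min = 3) {
  stopifnot(inherits(resid_meth, "methylation_data"), inherits(geno, "genotype_data"))
  if (!identical(rownames(resid_meth$values), rownames(geno$dosage)))
    stopf("methylation and genotype samples are not aligned")
  Y <- resid_meth$values
  sites <- resid_meth$sites
  snps <- geno$snps
  D <- geno$dosage
  mac <- pmin(colSums(D, na.rm = TRUE),
              colSums(2 - D, na.rm = TRUE))
  testable <- mac >= mac_min
  rows <- list()
  for (j in which(testable)) {
    g <- D[, j]
    for (i in seq_len(ncol(Y))) {
      a <- snp_assoc(Y[, i], g)
      if (is.null(a)) next
      same <- snps$chrom[j] == sites$chrom[i]
      dist <- if (same) snps$pos[j] - sites$pos[i] else NA_integer_
      rel <- if (same && abs(dist) <= cis_window) "cis" else "trans"
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = snps$id[j], site_id = sites$id[i],
        beta = a$beta, se = a$se, t = a$t, p = a$p, r2 = a$r2,
        relation = rel, distance = dist, stringsAsFactors = FALSE
      )
    }
  }
  assoc <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_id = character(), site_id = character(), beta = numeric(),
               se = numeric(), t = numeric(), p = numeric(), r2 = numeric(),
               relation = character(), distance = numeric())
  n_tests <- c(cis = sum(assoc$relation == "cis"),
               trans = sum(assoc$relation == "trans"))
  summ <- do.call(rbind, lapply(thresholds, function(th) {
    do.call(rbind, lapply(c("cis", "trans"), function(rel) {
      sub <- assoc[assoc$relation == rel, , drop = FALSE]
      sig <- sub$p < th
      data.frame(threshold = th, relation = rel, count = sum(sig),
                 count_expected = expected_count(nrow(sub), th),
                 count_sites = length(unique(sub$site_id[sig])),
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(assoc = assoc, summary = summ, n_tests = n_tests),
            class = "gwas_scan")
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat(sprintf("gwas_scan: %d cis and %d trans tests\n",
              x$n_tests["cis"], x$n_tests["trans"]))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Top cis SNP versus the regional estimate
#'
#' Pairs each significantly heritable site with its most significant cis
#' SNP (smallest p; ties broken by larger `r2`, then smaller genomic
#' position) and reports the ratio `r2_top / h2` together with the
#' fraction of sites where the region explains at least as much variance
#' as the single SNP (`ratio <= 1`).
#'
#' @param rh an [rh_scan()] result (or its `results` data.frame).
#' @param gwas a [gwas_scan()] result (or its `assoc` data.frame).
#' @param geno optional [genotype_data()] used only to order ties by SNP
#'   position; without it ties fall back to SNP id order.
#' @param alpha significance level for the regional estimate (0.05).
#' @return list: `pairs` (data.frame `site_id, snp_id, r2, h2, ratio`),
#'   `frac_region_ge_snp`, `n_skipped` (significant sites without a cis
#'   association).
#' @export
top_snp_vs_region <- function(rh, gwas, geno = NULL, alpha = 0.05) {
  res <- if (inherits(rh, "rh_scan")) rh$results else rh
  assoc <- if (inherits(gwas, "gwas_scan")) gwas$assoc else gwas
  sig <- res[res$p < alpha & res$h2 > 0, , drop = FALSE]
  cis <- assoc[assoc$relation == "cis", , drop = FALSE]
  if (!is.null(geno))
    cis$snp_pos <- geno$snps$pos[match(cis$snp_id, geno$snps$id)]
  else
    cis$snp_pos <- match(cis$snp_id, sort(unique(cis$snp_id)))
  pairs <- list(); skipped <- 0L
  for (i in seq_len(nrow(sig))) {
    sub <- cis[cis$site_id == sig$site_id[i], , drop = FALSE]
    if (!nrow(sub)) { skipped <- skipped + 1L; next }
    sub <- sub[order(sub$p, -sub$r2, sub$snp_pos), , drop = FALSE]
    top <- sub[1L, ]
    pairs[[length(pairs) + 1L]] <- data.frame(
      site_id = sig$site_id[i], snp_id = top$snp_id, r2 = top$r2,
      h2 = sig$h2[i], ratio = top$r2 / sig$h2[i], stringsAsFactors = FALSE
    )
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(site_id = character(), snp_id = character(), r2 = numeric(),
               h2 = numeric(), ratio = numeric())
  list(pairs = pairs,
       frac_region_ge_snp = if (nrow(pairs)) mean(pairs$ratio <= 1) else NA_real_,
       n_skipped = skipped)
}
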