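#' Standardize SNP dosages (VanRaden scaling)
#'
#' Column j of the output is `(g - 2 p_j) / sqrt(2 p_j (1 - p_j))` with
#' `p_j` the (sample) alternate-allele frequency.  Missing dosages are
#' imputed to `2 p_j` before standardization, i.e. to 0 after centering.
#' Monomorphic SNPs are dropped.
#'
#' @param dosage samples x SNPs dosage matrix (0/1/2/NA).
#' @param freqs optional allele frequencies; default: sample frequencies
#'   from non-missing calls.
#' @param warn warn when monomorphic SNPs are dropped.
#' @return standardized samples x SNPs matrix (possibly fewer columns).
#' @export
standardize_genotypes <- function(dosage, freqs = NULL, warn = TRUE) {
  dosage <- as.matrix(dosage)
  if (is.null(freqs)) freqs <- colMeans(dosage, na.rm = TRUE) / 2
  poly <- !is.na(freqs) & freqs > 0 & freqs < 1
  if (warn && any(!poly))
    warnf("dropping %d monomorphic SNPs before standardization", sum(!poly))
  d <- dosage[, poly, drop = FALSE]
  p <- freqs[poly]
  W <- sweep(d, 2, 2 * p)
  W[is.na(W)] <- 0
  sweep(W, 2, sqrt(2 * p * (1 - p)), `/`)
}

#' Regional genomic relationship matrix
#'
#' VanRaden GRM `A = W W' / N` over the `N` SNPs within `half_window` bp of
#' a genomic position (window inclusive at both endpoints, same chromosome
#' only), after monomorphic-SNP removal.
#'
#' @param geno a [genotype_data()].
#' @param center 1-based bp position of the focal CpG site.
#' @param chrom chromosome of the focal site (default: first chromosome in
#'   the genotype map).
#' @param half_window window half-width in bp (default 1e6).
#' @return list of class `grm` with `A` (n x n), `N` (SNP count) and
#'   `snp_ids`; `NULL` when the window holds no usable SNP.
#' @export
regional_grm <- function(geno, center, chrom = geno$snps$chrom[1],
                         half_window = 1e6) {
  stopifnot(inherits(geno, "genotype_data"))
  sel <- geno$snps$chrom == chrom &
    geno$snps$pos >= center - half_window &
    geno$snps$pos <= center + half_window
  if (!any(sel)) return(NULL)
  W <- standardize_genotypes(geno$dosage[, sel, drop = FALSE], warn = FALSE)
  if (ncol(W) == 0L) return(NULL)
  N <- ncol(W)
  structure(list(A = tcrossprod(W) / N, N = N, snp_ids = colnames(W)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d x %d from %d SNPs (mean diag %.3f)\n",
              nrow(x$A), ncol(x$A), x$N, mean(diag(x$A))))
  invisible(x)
}

#' REML fit of the one-GRM mixed model by profile likelihood
#'
#' Fits `y ~ N(X beta, A sigma_g^2 + I sigma_e^2)` by restricted maximum
#' likelihood, maximizing over `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`.
#' The GRM is eigendecomposed once (negative eigenvalues clipped to zero);
#' the restricted log-likelihood, with the total variance profiled out in
#' closed form, is evaluated on a `ngrid`-point grid over
#' `[0, 1 - 1e-6]` and the optimum refined by golden-section search to
#' `|dh2| < 1e-6`.  When the profile is maximized at the boundary the fit
#' reports `h2 = 0` (a flat profile, e.g. `A = I`, also lands there).
#'
#' @param y phenotype vector (length n).
#' @param X fixed-effect design matrix (n x p, including the intercept).
#' @param A genomic relationship matrix (n x n, symmetric PSD) or a `grm`
#'   object.
#' @param ngrid grid resolution (default 512).
#' @return list: `sigma_g2`, `sigma_e2`, `h2`, `ll` (restricted
#'   log-likelihood at the optimum), `ll_null` (at `h2 = 0`), `beta`,
#'   `beta_se` (GLS fixed effects at the optimum), `n_clipped` (negative
#'   eigenvalues clipped), `converged`.
#' @export
reml_fit <- function(y, X, A, ngrid = 512L) {
  if (inherits(A, "grm")) A <- A$A
  n <- length(y)
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(nrow(X) == n, nrow(A) == n, ncol(A) == n)
  if (n <= p) stopf("need more samples than fixed-effect columns")

  e <- eigen(A, symmetric = TRUE)
  d <- e$values
  n_clipped <- sum(d < 0)
  d[d < 0] <- 0
  U <- e$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)

  llfun <- function(h2) {
    lambda <- h2 * d + (1 - h2)
    w <- 1 / lambda
    Xw <- Xt * w
    A1 <- crossprod(Xt, Xw)
    b1 <- crossprod(Xw, yt)
    ch <- tryCatch(chol(A1), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    beta <- backsolve(ch, forwardsolve(t(ch), b1))
    r <- yt - Xt %*% beta
    q <- sum(r^2 * w)
    sig2 <- q / (n - p)
    if (sig2 <= 0) return(-Inf)
    -0.5 * ((n - p) * log(2 * pi * sig2) + sum(log(lambda)) +
              2 * sum(log(diag(ch))) + (n - p))
  }

  grid <- seq(0, 1 - 1e-6, length.out = ngrid)
  llg <- vapply(grid, llfun, numeric(1))
  i <- which.max(llg)
  h2 <- grid[i]
  ll <- llg[i]
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(ngrid, i + 1L)]
  if (hi > lo) {
    opt <- optimize(llfun, lower = lo, upper = hi, maximum = TRUE, tol = 1e-7)
    if (opt$objective > ll) { h2 <- opt$maximum; ll <- opt$objective }
  }
  ll_null <- llg[1]
  if (ll < ll_null) { h2 <- 0; ll <- ll_null }  # optimizer contract
  converged <- is.finite(ll)

  # report components and GLS fixed effects at the optimum
  lambda <- h2 * d + (1 - h2)
  w <- 1 / lambda
  A1 <- crossprod(Xt, Xt * w)
  b1 <- crossprod(Xt * w, yt)
  A1inv <- solve(A1)
  beta <- drop(A1inv %*% b1)
  r <- yt - Xt %*% beta
  sig2 <- sum(r^2 * w) / (n - p)
  beta_se <- sqrt(diag(A1inv) * sig2)
  names(beta) <- names(beta_se) <- colnames(X)
  list(sigma_g2 = h2 * sig2, sigma_e2 = (1 - h2) * sig2, h2 = h2,
       ll = ll, ll_null = ll_null, beta = beta, beta_se = beta_se,
       n_clipped = n_clipped, converged = converged)
}

#' Boundary-mixture likelihood-ratio p-value
#'
#' Because the null value of the genetic variance lies on the boundary of
#' the parameter space, the LRT statistic `T = 2 (ll_alt - ll_null)` is
#' distributed under the null as a 50:50 mixture of a point mass at zero
#' (chi-square with 0 df) and a chi-square with 1 df:
#' `p = 1` when `T = 0`, else `p = 0.5 * Pr(chi2_1 >= T)`.
#'
#' @param ll_alt,ll_null restricted log-likelihoods of the alternative and
#'   null (h2 = 0) fits.  Small negative `T` (> -1e-8) is clipped to 0.
#' @return p-value in (0, 1].
#' @export
lrt_pvalue <- function(ll_alt, ll_null) {
  T <- 2 * (ll_alt - ll_null)
  if (any(T < -1e-8)) stopf("ll_alt is smaller than ll_null beyond tolerance")
  T <- pmax(T, 0)
  ifelse(T == 0, 1, 0.5 * pchisq(T, df = 1, lower.tail = FALSE))
}

#' Regional heritability scan over CpG sites
#'
#' For each site, builds the +/-`half_window` VanRaden GRM, fits the mixed
#' model by [reml_fit()] with the covariates as fixed effects (or on
#' residualized phenotypes with an intercept-only design, if
#' `covariate_mode = "residualized"`), and tests `h2 > 0` with the 50:50
#' mixture LRT.  A site is declared heritable iff `p < alpha` with no
#' multiple-testing correction (a Benjamini-Hochberg column is emitted
#' alongside for reference).  Sites with an empty SNP window are skipped
#' and excluded from the summary denominator.
#'
#' @param meth a [methylation_data()] on the M scale.
#' @param geno a [genotype_data()] with samples aligned to `meth`.
#' @param covars optional covariate data.frame (see [residualize()]).
#' @param half_window window half-width in bp (1e6).
#' @param alpha nominal significance level (0.05).
#' @param covariate_mode `"fixed"` (covariates as fixed effects in the
#'   REML model, default) or `"residualized"` (pre-adjusted phenotypes).
#' @return list of class `rh_scan`: `results` (one row per tested site:
#'   `site_id, chrom, pos, win_start, win_end, n_snps, sigma_g2, sigma_e2,
#'   h2, ll_alt, ll_null, lrt, p, p_bh, converged`), `skipped` (site ids
#'   with empty windows) and `summary` (list: `n_tested, n_skipped,
#'   prop_significant, mean_h2_sig, median_h2_sig, alpha`).
#' @export
rh_scan <- function(meth, geno, covars = NULL, half_window = 1e6,
                    alpha = 0.05, covariate_mode = c("fixed", "residualized")) {
  stopifnot(inherits(meth, "methylation_data"), inherits(geno, "genotype_data"))
  covariate_mode <- match.arg(covariate_mode)
  if (!identical(rownames(meth$values), rownames(geno$dosage)))
    stopf("methylation and genotype samples are not aligned")
  n <- nrow(meth$values)
  Y <- meth$values
  if (covariate_mode == "residualized" && !is.null(covars)) {
    Y <- residualize(meth, covars)$meth$values
    # keep the covariate design in X: the GLS coefficients are ~0 on
    # residualized data, but the restricted likelihood then carries the
    # same n - p degrees of freedom as the fixed-effect route
    X <- build_design(covars)
  } else if (!is.null(covars)) {
    X <- build_design(covars)
  } else {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }

  sites <- meth$sites
  rows <- vector("list", nrow(sites))
  skipped <- character(0)
  for (i in seq_len(nrow(sites))) {
    grm <- regional_grm(geno, sites$pos[i], chrom = sites$chrom[i],
                        half_window = half_window)
    if (is.null(grm)) { skipped <- c(skipped, sites$id[i]); next }
    fit <- reml_fit(Y[, i], X, grm)
    pv <- lrt_pvalue(fit$ll, fit$ll_null)
    rows[[i]] <- data.frame(
      site_id = sites$id[i], chrom = sites$chrom[i], pos = sites$pos[i],
      win_start = sites$pos[i] - half_window,
      win_end = sites$pos[i] + half_window,
      n_snps = grm$N, sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
      h2 = fit$h2, ll_alt = fit$ll, ll_null = fit$ll_null,
      lrt = max(0, 2 * (fit$ll - fit$ll_null)), p = pv,
      converged = fit$converged, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res)) stopf("no site had a non-empty SNP window")
  res$p_bh <- stats::p.adjust(res$p, method = "BH")
  # p is capped at 1 (boundary point mass), so alpha = 1 means "all"
  sig <- if (alpha >= 1) res$converged else res$p < alpha & res$converged
  summary <- list(
    n_tested = nrow(res), n_skipped = length(skipped),
    prop_significant = mean(sig),
    mean_h2_sig = if (any(sig)) mean(res$h2[sig]) else NA_real_,
    median_h2_sig = if (any(sig)) stats::median(res$h2[sig]) else NA_real_,
    alpha = alpha
  )
  structure(list(results = res, skipped = skipped, summary = summary),
            class = "rh_scan")
}

#' @export
print.rh_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("rh_scan: %d sites tested (%d skipped); %.2f%% heritable at ",
                     "alpha = %g; mean h2 among significant = %.3f\n"),
              s$n_tested, s$n_skipped, 100 * s$prop_significant, s$alpha,
              s$mean_h2_sig))
  invisible(x)
}

#' Proportion of the regional heritability explained by one SNP
#'
#' `1 - h2_full / h2_all`, the drop in the regional estimate when the
#' focal SNP is moved from the GRM to a fixed effect.
#'
#' @param h2_all regional h2 with all window SNPs in the GRM.
#' @param h2_full regional h2 with the focal SNP excluded from the GRM and
#'   fitted as a fixed effect.
#' @return proportion (can be negative; `NA` when `h2_all` is 0).
#' @export
prop_h2_explained <- function(h2_all, h2_full) {
  ifelse(h2_all > 0, 1 - h2_full / h2_all, NA_real_)
}

#' Fixed-effect decomposition of a regional heritability estimate
#'
#' Three REML fits around a named SNP: `h2_all` (all window SNPs in the
#' GRM), `h2_reduced` (GRM excluding the SNP), and `h2_full` (GRM excluding
#' the SNP, with the SNP dosage added as a fixed-effect column).  The SNP
#' effect is reported per copy of the minor allele (sample frequency;
#' a tie at 0.5 keeps the alternate allele) with its standard error, and
#' the proportion of the regional estimate explained by the SNP is
#' `1 - h2_full / h2_all`.
#'
#' @param meth a [methylation_data()] (M scale).
#' @param geno a [genotype_data()], samples aligned with `meth`.
#' @param site_id focal CpG site id.
#' @param snp_id focal SNP id; must lie within the window.
#' @param covars optional covariate data.frame.
#' @param half_window window half-width in bp (1e6).
#' @return one-row data.frame: `site_id, snp_id, h2_all, p_all, h2_full,
#'   p_full, h2_reduced, p_reduced, snp_beta, snp_se, prop_explained`.
#' @export
snp_fixed_decomposition <- function(meth, geno, site_id, snp_id,
                                    covars = NULL, half_window = 1e6) {
  stopifnot(inherits(meth, "methylation_data"), inherits(geno, "genotype_data"))
  si <- match(site_id, meth$sites$id)
  if (is.na(si)) stopf("unknown site id '%s'", site_id)
  pos <- meth$sites$pos[si]
  chrom <- meth$sites$chrom[si]
  y <- meth$values[, si]
  n <- length(y)
  X <- if (is.null(covars)) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
       else build_design(covars)

  grm_all <- regional_grm(geno, pos, chrom = chrom, half_window = half_window)
  if (is.null(grm_all) || !(snp_id %in% grm_all$snp_ids))
    stopf("SNP '%s' is not a polymorphic SNP inside the window", snp_id)
  keep <- setdiff(grm_all$snp_ids, snp_id)
  sub <- subset_geno(geno, snps = match(keep, geno$snps$id))
  grm_red <- regional_grm(sub, pos, chrom = chrom, half_window = half_window)

  g <- geno$dosage[, snp_id]
  p_alt <- mean(g, na.rm = TRUE) / 2
  if (p_alt > 0.5) g <- 2 - g  # code per minor allele; tie keeps alt
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  Xf <- cbind(X, snp = g)

  fit_all <- reml_fit(y, X, grm_all)
  fit_red <- reml_fit(y, X, grm_red)
  fit_full <- reml_fit(y, Xf, grm_red)
  data.frame(
    site_id = site_id, snp_id = snp_id,
    h2_all = fit_all$h2, p_all = lrt_pvalue(fit_all$ll, fit_all$ll_null),
    h2_full = fit_full$h2, p_full = lrt_pvalue(fit_full$ll, fit_full$ll_null),
    h2_reduced = fit_red$h2, p_reduced = lrt_pvalue(fit_red$ll, fit_red$ll_null),
    snp_beta = unname(fit_full$beta["snp"]),
    snp_se = unname(fit_full$beta_se["snp"]),
    prop_explained = prop_h2_explained(fit_all$h2, fit_full$h2),
    stringsAsFactors = FALSE
  )
}

#' Simulation study of the regional heritability estimator
#'
#' Generates `n_sites` independent CpG sites, each with a fresh panel of
#' `n_snps` Hardy-Weinberg SNPs in a +/-1 Mb window (first-order LD,
#' [sim_genotypes()]), a phenotype `y = X beta + W u + e` with the realized
#' genetic variance fraction pinned to `true_h2`
#' ([sim_site_phenotype()]), and covariate effects; then estimates h2 by
#' [regional_grm()] + [reml_fit()] with the covariates as fixed effects and
#' computes the mixture-LRT p-value.  This is the calibration /
#' parameter-recovery harness.
#'
#' @param n_sites number of simulated sites.
#' @param true_h2 true local heritability (scalar, in [0, 1)).
#' @param n_samples cohort size (default 132).
#' @param n_snps SNPs per window (default 300).
#' @param n_causal causal SNPs per site (default 5; ignored when
#'   `true_h2 = 0`).
#' @param seed integer seed.
#' @param ... further arguments passed to [sim_config()] (e.g. `maf_range`,
#'   `ld_rho`, `covariate_effects`).
#' @return data.frame: `site, true_h2, h2_hat, p, n_snps`.
#' @export
rh_sim_study <- function(n_sites, true_h2, n_samples = 132, n_snps = 300,
                         n_causal = 5, seed, ...) {
  cfg <- sim_config(n_samples = n_samples, chrom_length = 2e6 + 1,
                    n_sites = 1, h2_dist = list(type = "point", value = true_h2),
                    n_causal_per_site = n_causal, seed = seed, ...)
  set.seed(cfg$seed)
  covars <- sim_covariates(n_samples)
  xb <- covariate_signal(covars, cfg$covariate_effects)
  X <- build_design(covars)
  center <- 1e6 + 1
  out <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    sim <- sim_genotypes_impl(cfg, n_snps = n_snps)
    ph <- sim_site_phenotype(sim$geno$dosage, true_h2, n_causal, cfg$sigma_e2)
    y <- xb + ph$y_rand
    grm <- regional_grm(sim$geno, center)
    fit <- reml_fit(y, X, grm)
    out[[s]] <- data.frame(site = s, true_h2 = true_h2, h2_hat = fit$h2,
                           p = lrt_pvalue(fit$ll, fit$ll_null), n_snps = grm$N)
  }
  do.call(rbind, out)
}
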