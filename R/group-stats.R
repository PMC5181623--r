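#' Welch two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom
#' (wraps [stats::t.test()]).  When both groups are constant: p = 1 if the
#' means are equal, otherwise the difference is deterministic and p = 0.
#'
#' @param x,y numeric samples (each n >= 2).
#' @return list `t, df, p`.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (sd(x) == 0 && sd(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (eq) 0 else Inf * sign(mean(x) - mean(y)),
                df = NA_real_, p = if (eq) 1 else 0))
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Asymptotic two-sided KS test (wraps [stats::ks.test()] with
#' `exact = FALSE`); ties produce the usual warning-free approximate p.
#'
#' @param x,y numeric samples.
#' @return list `D, p`.
#' @export
ks_2samp <- function(x, y) {
  ht <- suppressWarnings(ks.test(x, y, exact = FALSE))
  list(D = unname(ht$statistic), p = ht$p.value)
}

#' Two-proportion test
#'
#' Two-sided pooled-variance test of equal proportions with Yates
#' continuity correction by default (wraps [stats::prop.test()]).
#'
#' @param k1,n1,k2,n2 successes and totals in the two groups.
#' @param correct apply the continuity correction (default TRUE).
#' @return list `statistic` (the chi-squared statistic, i.e. z squared),
#'   `p`, `p1`, `p2`.
#' @export
two_prop_test <- function(k1, n1, k2, n2, correct = TRUE) {
  if (k1 > n1 || k2 > n2) stopf("successes cannot exceed totals")
  stopifnot(n1 > 0, n2 > 0)
  if (k1 / n1 == k2 / n2)   # identical proportions: statistic floored at 0
    return(list(statistic = 0, p = 1, p1 = k1 / n1, p2 = k2 / n2))
  ht <- suppressWarnings(prop.test(c(k1, k2), c(n1, n2), correct = correct))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       p1 = k1 / n1, p2 = k2 / n2)
}

#' Contextual group summaries and pairwise tests
#'
#' Builds, for the eight island/sea-by-genic groups and the six
#' CpG-density classes, the per-group summary (site count; mean, median
#' and variance of the per-site mean methylation; mean residual variance;
#' proportion heritable; mean h2 among significant sites; mean genetic
#' variance), all pairwise tests among the eight groups (Welch t and KS on
#' the site means, Welch t on residual variances, two-proportion test on
#' the heritable fractions), and the per-density-class Pearson correlation
#' between the proportion heritable and the mean genetic variance across
#' the four genic groups (a descriptive 4-point correlation).
#'
#' @param site_stats data.frame with one row per site: `site_id, mean_m,
#'   resid_var, h2, p, sigma_g2, density, genic` (`density` values
#'   `island`/`sea` define the eight groups; other density classes are
#'   summarized in the density table only).
#' @param alpha significance level used for "heritable" (0.05).
#' @return list of class `context_summary`: `groups` (8-group summary),
#'   `density` (6-class summary), `pairwise` (long data.frame of tests),
#'   `prop_vs_genvar` (per density class: Pearson r).
#' @export
context_summaries <- function(site_stats, alpha = 0.05) {
  need <- c("site_id", "mean_m", "resid_var", "h2", "p", "sigma_g2",
            "density", "genic")
  if (!all(need %in% names(site_stats)))
    stopf("site_stats needs columns %s", paste(need, collapse = ", "))
  ss <- site_stats
  ss$heritable <- ss$p < alpha

  summarize_group <- function(d) {
    sig <- d$heritable
    data.frame(
      n_sites = nrow(d),
      mean_m = mean(d$mean_m), median_m = stats::median(d$mean_m),
      var_m = if (nrow(d) > 1) var(d$mean_m) else NA_real_,
      mean_resid_var = mean(d$resid_var),
      prop_heritable = mean(sig),
      mean_h2_sig = if (any(sig)) mean(d$h2[sig]) else NA_real_,
      mean_genetic_var = mean(d$sigma_g2)
    )
  }

  eight <- ss[ss$density %in% c("island", "sea"), , drop = FALSE]
  eight$group <- paste(eight$density, eight$genic, sep = ".")
  glev <- as.vector(outer(c("island", "sea"), GENIC_LEVELS, paste, sep = "."))
  groups <- do.call(rbind, lapply(glev, function(g) {
    d <- eight[eight$group == g, , drop = FALSE]
    out <- if (nrow(d)) summarize_group(d) else
      data.frame(n_sites = 0L, mean_m = NA_real_, median_m = NA_real_,
                 var_m = NA_real_, mean_resid_var = NA_real_,
                 prop_heritable = NA_real_, mean_h2_sig = NA_real_,
                 mean_genetic_var = NA_real_)
    cbind(data.frame(group = g), out)
  }))

  density <- do.call(rbind, lapply(DENSITY_LEVELS, function(dc) {
    d <- ss[ss$density == dc, , drop = FALSE]
    out <- if (nrow(d)) summarize_group(d) else
      data.frame(n_sites = 0L, mean_m = NA_real_, median_m = NA_real_,
                 var_m = NA_real_, mean_resid_var = NA_real_,
                 prop_heritable = NA_real_, mean_h2_sig = NA_real_,
                 mean_genetic_var = NA_real_)
    cbind(data.frame(density = dc), out)
  }))

  present <- glev[vapply(glev, function(g) sum(eight$group == g) >= 2, logical(1))]
  pw <- list()
  if (length(present) >= 2) {
    cmb <- utils::combn(present, 2)
    for (k in seq_len(ncol(cmb))) {
      a <- eight[eight$group == cmb[1, k], ]
      b <- eight[eight$group == cmb[2, k], ]
      wt <- welch_t(a$mean_m, b$mean_m)
      ks <- ks_2samp(a$mean_m, b$mean_m)
      rv <- welch_t(a$resid_var, b$resid_var)
      pp <- two_prop_test(sum(a$heritable), nrow(a), sum(b$heritable), nrow(b))
      pw[[k]] <- data.frame(
        group1 = cmb[1, k], group2 = cmb[2, k],
        welch_t_mean = wt$t, welch_p_mean = wt$p,
        ks_D = ks$D, ks_p = ks$p,
        welch_t_residvar = rv$t, welch_p_residvar = rv$p,
        prop_stat = pp$statistic, prop_p = pp$p,
        stringsAsFactors = FALSE
      )
    }
  }
  pairwise <- if (length(pw)) do.call(rbind, pw) else NULL

  # 4-point descriptive correlation per density class (island, sea)
  pv <- do.call(rbind, lapply(c("island", "sea"), function(dc) {
    g <- groups[startsWith(groups$group, paste0(dc, ".")), ]
    ok <- stats::complete.cases(g[, c("prop_heritable", "mean_genetic_var")])
    r <- if (sum(ok) >= 3 && sd(g$prop_heritable[ok]) > 0 &&
             sd(g$mean_genetic_var[ok]) > 0)
      cor(g$prop_heritable[ok], g$mean_genetic_var[ok]) else NA_real_
    data.frame(density = dc, pearson_r = r, n_points = nrow(g))
  }))

  structure(list(groups = groups, density = density, pairwise = pairwise,
                 prop_vs_genvar = pv, alpha = alpha),
            class = "context_summary")
}

#' @export
print.context_summary <- function(x, ...) {
  cat("Eight contextual groups:\n")
  print(x$groups, row.names = FALSE, digits = 3)
  cat("\nProportion-heritable vs mean genetic variance (4 points each):\n")
  print(x$prop_vs_genvar, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Predicted change in h2 from the SNP-count regression
#'
#' The fitted slope of the heritability-on-window-SNP-count regression
#' times a SNP count: the expected increase in h2 attributable to a window
#' of that size.
#'
#' @param slope regression slope (h2 per SNP).
#' @param n_snps window SNP count(s).
#' @return predicted increase(s) in h2.
#' @export
predict_h2_increase <- function(slope, n_snps) slope * n_snps

#' Regressions of the heritability estimate on window size and context
#'
#' Among significantly heritable sites: (a) OLS of h2 on the window SNP
#' count (slope, R2, p); (b) OLS of h2 on the site's residual variance
#' (R2, p); (c) sequential (type-I) ANOVA F test for the genomic-context
#' factor after residual variance.
#'
#' @param rh an [rh_scan()] result or its `results` data.frame (columns
#'   `h2, p, n_snps, site_id`).
#' @param resid_var named per-site residual variances.
#' @param context per-site context factor (e.g. the eight groups), named
#'   by or aligned with `site_id`.
#' @param alpha significance level (0.05).
#' @return list: `snp_count` (`slope, r2, p, fit`), `resid_var`
#'   (`slope, r2, p`), `context_anova` (`F, p`), `n_sig`; `NULL` when
#'   fewer than 3 significant sites.
#' @export
h2_variance_partition <- function(rh, resid_var, context, alpha = 0.05) {
  res <- if (inherits(rh, "rh_scan")) rh$results else rh
  sig <- res[res$p < alpha, , drop = FALSE]
  if (nrow(sig) < 3) return(NULL)
  d <- data.frame(h2 = sig$h2, n_snps = sig$n_snps,
                  resid_var = resid_var[sig$site_id],
                  context = factor(context[sig$site_id]))
  f1 <- lm(h2 ~ n_snps, data = d)
  s1 <- summary(f1)
  f2 <- lm(h2 ~ resid_var, data = d)
  s2 <- summary(f2)
  out <- list(
    snp_count = list(slope = unname(coef(f1)[2]), r2 = s1$r.squared,
                     p = s1$coefficients[2, 4], fit = f1),
    resid_var = list(slope = unname(coef(f2)[2]), r2 = s2$r.squared,
                     p = s2$coefficients[2, 4]),
    n_sig = nrow(d)
  )
  if (nlevels(droplevels(d$context)) >= 2) {
    a <- anova(lm(h2 ~ resid_var + context, data = d))
    out$context_anova <- list(F = a["context", "F value"],
                              p = a["context", "Pr(>F)"])
  } else {
    out$context_anova <- list(F = NA_real_, p = NA_real_)
  }
  out
}

#' Compare heritability inside and outside disease risk regions
#'
#' Partitions sites by overlap with the union of +/-`half_window` regions
#' around a list of risk SNPs (boundary inclusive: a site exactly
#' `half_window` bp from a risk SNP is within) and compares the heritable
#' proportions with a two-proportion test, also reporting the mean h2 of
#' significant sites per partition.
#'
#' @param rh an [rh_scan()] result or its `results` data.frame (needs
#'   `chrom, pos, h2, p`).
#' @param risk_snps data.frame `chrom, pos, id` of risk variants (an empty
#'   frame puts every site outwith).
#' @param half_window region half-width in bp (1e6).
#' @param alpha significance level (0.05).
#' @return list: `within`, `outwith` (each `n, prop_heritable,
#'   mean_h2_sig`), `test` (two-proportion, `NULL` when a partition is
#'   empty).
#' @export
risk_region_compare <- function(rh, risk_snps, half_window = 1e6, alpha = 0.05) {
  res <- if (inherits(rh, "rh_scan")) rh$results else rh
  within <- rep(FALSE, nrow(res))
  if (!is.null(risk_snps) && nrow(risk_snps)) {
    for (k in seq_len(nrow(risk_snps))) {
      within <- within | (res$chrom == risk_snps$chrom[k] &
                            abs(res$pos - risk_snps$pos[k]) <= half_window)
    }
  }
  part <- function(d) {
    sig <- d$p < alpha
    list(n = nrow(d),
         prop_heritable = if (nrow(d)) mean(sig) else NA_real_,
         mean_h2_sig = if (any(sig)) mean(d$h2[sig]) else NA_real_)
  }
  win <- part(res[within, , drop = FALSE])
  out <- part(res[!within, , drop = FALSE])
  test <- if (win$n > 0 && out$n > 0)
    two_prop_test(round(win$prop_heritable * win$n), win$n,
                  round(out$prop_heritable * out$n), out$n) else NULL
  list(within = win, outwith = out, test = test)
}
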