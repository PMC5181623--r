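test_that("genotype standardization follows the VanRaden formula", {
  d <- matrix(c(2, 1, 0, NA), 4, 1)
  # sample frequency from non-missing calls: p = 3/6 = 0.5
  W <- suppressWarnings(standardize_genotypes(d))
  expect_equal(W[1, 1], (2 - 1) / sqrt(0.5))   # ~ 1.41421
  expect_equal(W[2, 1], 0)                     # heterozygote at p = 0.5
  expect_equal(W[4, 1], 0)                     # missing -> imputed to 2p
  # monomorphic SNPs dropped with a warning
  expect_warning(W2 <- standardize_genotypes(cbind(d, 2)), "monomorphic")
  expect_equal(ncol(W2), 1)
})

test_that("regional GRM matches the per-pair formula oracle", {
  g <- make_geno(15, runif(40, 0.1, 0.5), spacing = 40000, seed = 31)
  grm <- regional_grm(g, center = 8e5, half_window = 1e6)
  A_or <- grm_pair_oracle(g$dosage[, g$snps$pos >= 8e5 - 1e6 &
                                     g$snps$pos <= 8e5 + 1e6, drop = FALSE])
  expect_lt(max(abs(grm$A - A_or)), 1e-10)
  expect_true(isSymmetric(grm$A))
  # mean diagonal ~ 1 for HWE genotypes
  g2 <- make_geno(150, runif(200, 0.1, 0.5), spacing = 5000, seed = 32)
  grm2 <- regional_grm(g2, center = 5e5)
  expect_lt(abs(mean(diag(grm2$A)) - 1), 0.1)
  # invariant to SNP order
  perm <- sample(ncol(g$dosage))
  gp <- genotype_data(g$dosage[, perm][, order(perm)], g$snps)
  expect_equal(regional_grm(gp, 8e5)$A, grm$A)
  # window containment: doubling the window never decreases N
  expect_gte(regional_grm(g, 8e5, half_window = 2e6)$N, grm$N)
  # degenerate constructed case: one SNP, dosages (2, 0) -> p = 0.5,
  # w = (+-1)/sqrt(0.5), A = [[2,-2],[-2,2]]
  g1 <- genotype_data(matrix(c(2, 0), 2, 1,
                             dimnames = list(c("s1", "s2"), "snp1")),
                      data.frame(chrom = "chr1", pos = 100, id = "snp1"))
  expect_equal(regional_grm(g1, 100)$A,
               matrix(c(2, -2, -2, 2), 2, 2, dimnames = list(c("s1","s2"), c("s1","s2"))))
  # empty window -> sentinel
  expect_null(regional_grm(g, 1e8))
})

test_that("REML optimum matches the dense grid-search oracle", {
  set.seed(77)
  for (k in 1:20) {
    n <- 60
    g <- make_geno(n, runif(60, 0.1, 0.5), spacing = 10000, seed = 100 + k)
    grm <- regional_grm(g, 3e5)
    X <- cbind(1, rnorm(n))
    h2_true <- runif(1, 0, 0.9)
    L <- chol(h2_true * grm$A + (1 - h2_true) * diag(n) + 1e-10 * diag(n))
    y <- drop(X %*% c(1, 0.5)) + drop(crossprod(L, rnorm(n)))
    fit <- reml_fit(y, X, grm)
    h2_or <- reml_grid_oracle(y, X, grm$A)
    expect_lt(abs(fit$h2 - h2_or), 1e-3)
    # the two likelihood routes agree at the optimum as well
    expect_equal(fit$ll, reml_ll_direct(fit$h2, y, X, grm$A),
                 tolerance = 1e-6)
    expect_gte(fit$ll, fit$ll_null)
  }
})

test_that("identity GRM yields a flat profile reported at h2 = 0", {
  set.seed(5)
  n <- 40
  y <- rnorm(n)
  X <- matrix(1, n, 1)
  fit <- reml_fit(y, X, diag(n))
  expect_equal(fit$h2, 0)
  expect_equal(fit$ll, fit$ll_null)
  expect_equal(lrt_pvalue(fit$ll, fit$ll_null), 1)
})

test_that("mixture LRT p-values follow the 50:50 boundary distribution", {
  expect_equal(lrt_pvalue(0, 0), 1)
  # T = 3.841459 (the chi2_1 95th percentile) -> p = 0.025
  expect_equal(lrt_pvalue(3.841459 / 2, 0), 0.025, tolerance = 1e-6)
  # p <= 0.5 whenever T > 0
  for (T in c(1e-6, 0.5, 2, 10))
    expect_lte(lrt_pvalue(T / 2, 0), 0.5)
  expect_error(lrt_pvalue(0, 1), "smaller")
})

test_that("h2 is invariant to affine rescaling of the phenotype", {
  set.seed(9)
  n <- 50
  g <- make_geno(n, runif(50, 0.2, 0.5), spacing = 10000, seed = 41)
  grm <- regional_grm(g, 2.5e5)
  X <- matrix(1, n, 1)
  y <- rnorm(n) + g$dosage[, 10] * 0.8
  f1 <- reml_fit(y, X, grm)
  f2 <- reml_fit(3.7 * y - 11, X, grm)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-5)
  expect_equal(f2$sigma_g2, 3.7^2 * f1$sigma_g2, tolerance = 1e-4)
})

test_that("rh_scan summarizes sites and honours alpha", {
  cfg <- sim_config(seed = 51, n_sites = 8, n_samples = 60,
                    chrom_length = 1e6,
                    h2_dist = list(type = "point", value = 0.6),
                    n_genes = 20, n_causal_per_site = 3)
  annot <- sim_annotation(cfg)
  g <- sim_genotypes(cfg)
  m <- sim_methylation(g$geno, annot, cfg)
  scan <- rh_scan(m$meth, g$geno, m$covars)
  expect_equal(nrow(scan$results), 8)
  expect_true(all(scan$results$h2 >= 0 & scan$results$h2 < 1))
  expect_true(all(scan$results$lrt >= 0))
  expect_true(all(scan$results$p > 0 & scan$results$p <= 1))
  expect_equal(scan$results$h2,
               scan$results$sigma_g2 /
                 (scan$results$sigma_g2 + scan$results$sigma_e2),
               tolerance = 1e-8)
  # alpha = 1 declares every converged site significant
  scan1 <- rh_scan(m$meth, g$geno, m$covars, alpha = 1)
  expect_equal(scan1$summary$prop_significant, 1)
})

test_that("estimates recover the simulated heritability at n = 132", {
  d1 <- rh_sim_study(120, 0.1, seed = 61)
  expect_lt(abs(mean(d1$h2_hat) - 0.1), 0.05)
  d6 <- rh_sim_study(120, 0.6, seed = 62)
  expect_lt(abs(mean(d6$h2_hat) - 0.6), 0.05)
  # strong truth is detected nearly always
  expect_gt(mean(d6$p < 0.05), 0.5)
})

test_that("covariates as fixed effects vs pre-residualization agree", {
  cfg <- sim_config(seed = 71, n_sites = 20, n_samples = 132,
                    chrom_length = 1e6, n_genes = 20,
                    h2_dist = list(type = "point", value = 0.4))
  annot <- sim_annotation(cfg)
  g <- sim_genotypes(cfg)
  m <- sim_methylation(g$geno, annot, cfg)
  s_fix <- rh_scan(m$meth, g$geno, m$covars, covariate_mode = "fixed")
  s_res <- rh_scan(m$meth, g$geno, m$covars, covariate_mode = "residualized")
  expect_lt(mean(abs(s_fix$results$h2 - s_res$results$h2)), 0.02)
})

test_that("fixed-effect decomposition isolates a causal SNP", {
  cfg <- sim_config(seed = 81, n_sites = 2, n_samples = 132,
                    chrom_length = 1e6, n_genes = 15,
                    h2_dist = list(type = "point", value = 0.6),
                    n_causal_per_site = 1,
                    covariate_effects = c(sex = 0, age = 0))
  annot <- sim_annotation(cfg)
  g <- sim_genotypes(cfg)
  m <- sim_methylation(g$geno, annot, cfg)
  site <- m$truth$site_id[1]
  causal <- m$truth$causal_snps[1]
  dec <- snp_fixed_decomposition(m$meth, g$geno, site, causal)
  expect_true(dec$prop_explained <= 1)
  # removing the single causal SNP as a fixed effect explains most of h2
  expect_gt(dec$prop_explained, 0.5)
  # a null SNP leaves the full and reduced fits close
  far <- setdiff(regional_grm(g$geno, m$meth$sites$pos[1])$snp_ids,
                 causal)
  null_snp <- far[length(far)]
  dec0 <- snp_fixed_decomposition(m$meth, g$geno, site, null_snp)
  expect_lt(abs(dec0$h2_full - dec0$h2_reduced), 0.1)
  # the worked arithmetic of the decomposition
  expect_equal(prop_h2_explained(0.307, 0.025), 1 - 0.025 / 0.307)
  expect_true(is.na(prop_h2_explained(0, 0.1)))
})
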