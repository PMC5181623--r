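test_that("single-pair association matches OLS identities", {
  set.seed(1)
  g <- rbinom(50, 2, 0.4)
  y <- 2 * g
  a <- snp_assoc(y, g)
  expect_equal(a$r2, 1)
  expect_equal(a$beta, 2)
  expect_lt(a$p, 1e-100)
  # t^2 equals the ANOVA F of the same regression
  y2 <- 0.3 * g + rnorm(50)
  a2 <- snp_assoc(y2, g)
  f <- anova(lm(y2 ~ g))[["F value"]][1]
  expect_equal(a2$t^2, f, tolerance = 1e-10)
  expect_equal(a2$beta, unname(coef(lm(y2 ~ g))[2]), tolerance = 1e-12)
  # joint permutation leaves the result unchanged
  perm <- sample(50)
  a3 <- snp_assoc(y2[perm], g[perm])
  expect_equal(a3$beta, a2$beta)
  expect_equal(a3$p, a2$p)
  # sentinels
  expect_null(snp_assoc(y2, rep(1, 50)))
  expect_null(snp_assoc(c(1, 2), c(0, 1)))
  # missing dosages dropped pairwise
  gna <- g; gna[1:5] <- NA
  expect_equal(snp_assoc(y2, gna)$n, 45)
})

test_that("null association p-values are uniform", {
  set.seed(2)
  g <- rbinom(500, 2, 0.3)
  ps <- replicate(200, snp_assoc(rnorm(500), g)$p)
  expect_gt(ks.test(ps, "punif")$p.value, 1e-3)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("expected counts are the independence product", {
  expect_equal(expected_count(1.338e11, 5e-8), 6690)
  expect_equal(expected_count(1e6, 0), 0)
  expect_equal(expected_count(1 / 5e-4, 5e-4), 1)
})

test_that("gwas scan partitions cis/trans and counts are monotone", {
  set.seed(3)
  n <- 80
  d <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.4), rbinom(n, 2, 0.5))
  rownames(d) <- sprintf("s%04d", 1:n)
  snps <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     pos = c(5e5, 2.2e6, 5e5),
                     id = c("sA", "sB", "sC"))
  g <- genotype_data(d, snps)
  v <- matrix(rnorm(n * 2), n, 2, dimnames = list(rownames(d), NULL))
  v[, 1] <- v[, 1] + d[, 1] * 2
  m <- methylation_data(v, data.frame(chrom = "chr1", pos = c(1e6, 1.4e6),
                                      id = c("cg1", "cg2")))
  scan <- gwas_scan(m, g, thresholds = c(5e-2, 5e-4, 5e-8))
  a <- scan$assoc
  # exhaustive, exclusive partition
  expect_equal(nrow(a), 6)
  expect_true(all(a$relation %in% c("cis", "trans")))
  # sA is 5e5 from cg1 (cis); sB is 1.2e6 away (trans); sC other chrom
  expect_equal(a$relation[a$snp_id == "sA" & a$site_id == "cg1"], "cis")
  expect_equal(a$relation[a$snp_id == "sB" & a$site_id == "cg1"], "trans")
  expect_equal(a$relation[a$snp_id == "sC" & a$site_id == "cg1"], "trans")
  expect_true(is.na(a$distance[a$snp_id == "sC"][1]))
  # boundary: exactly 1 Mb is cis
  expect_equal(a$relation[a$snp_id == "sB" & a$site_id == "cg2"], "cis")
  # counts monotone non-increasing over descending thresholds
  for (rel in c("cis", "trans")) {
    cnt <- scan$summary$count[scan$summary$relation == rel]
    expect_true(all(diff(cnt) <= 0))
  }
  # the strong cis effect is found
  expect_equal(scan$summary$count_sites[scan$summary$threshold == 5e-8 &
                                          scan$summary$relation == "cis"], 1)
  # single site, single SNP reduces to the single test
  m1 <- subset_meth <- methylation_data(v[, 1, drop = FALSE],
                                        m$sites[1, , drop = FALSE])
  g1 <- genotype_data(d[, 1, drop = FALSE], snps[1, , drop = FALSE])
  s1 <- gwas_scan(m1, g1, thresholds = 5e-2)
  a1 <- snp_assoc(v[, 1], d[, 1])
  expect_equal(s1$assoc$p, a1$p)
  expect_equal(s1$summary$count[s1$summary$relation == "cis"], 1)
})

test_that("under the null, observed counts match expectations", {
  set.seed(4)
  n <- 200
  m_snps <- 40; m_sites <- 10
  d <- vapply(runif(m_snps, 0.2, 0.5), function(p) rbinom(n, 2, p), numeric(n))
  rownames(d) <- sprintf("s%04d", 1:n)
  g <- genotype_data(d, data.frame(chrom = "chr1", pos = (1:m_snps) * 1e4,
                                   id = sprintf("snp%05d", 1:m_snps)))
  v <- matrix(rnorm(n * m_sites), n, m_sites, dimnames = list(rownames(d), NULL))
  m <- methylation_data(v, data.frame(chrom = "chr1",
                                      pos = (1:m_sites) * 3e4 + 5e3,
                                      id = sprintf("cg%03d", 1:m_sites)))
  scan <- gwas_scan(m, g, thresholds = 5e-2)
  s <- scan$summary[scan$summary$relation == "cis", ]
  expect_lt(abs(s$count - s$count_expected), 4 * sqrt(s$count_expected) + 1)
})

test_that("top SNP vs region ratio behaves across architectures", {
  # one causal SNP, large n: the top SNP explains about the whole region
  cfg <- sim_config(seed = 91, n_sites = 3, n_samples = 400,
                    chrom_length = 1e6, n_genes = 15,
                    h2_dist = list(type = "point", value = 0.5),
                    n_causal_per_site = 1,
                    covariate_effects = c(sex = 0, age = 0))
  annot <- sim_annotation(cfg)
  g <- sim_genotypes(cfg)
  m <- sim_methylation(g$geno, annot, cfg)
  rh <- rh_scan(m$meth, g$geno)
  gw <- gwas_scan(m$meth, g$geno, thresholds = 5e-2)
  top <- top_snp_vs_region(rh, gw, g$geno)
  expect_true(all(abs(top$pairs$ratio - 1) < 0.35))
  # polygenic window: the top single SNP explains less than the region
  cfgP <- sim_config(seed = 92, n_sites = 3, n_samples = 400,
                     chrom_length = 1e6, n_genes = 15,
                     h2_dist = list(type = "point", value = 0.5),
                     n_causal_per_site = 40, ld_rho = 0,
                     covariate_effects = c(sex = 0, age = 0))
  annotP <- sim_annotation(cfgP)
  gP <- sim_genotypes(cfgP)
  mP <- sim_methylation(gP$geno, annotP, cfgP)
  rhP <- rh_scan(mP$meth, gP$geno)
  gwP <- gwas_scan(mP$meth, gP$geno, thresholds = 5e-2)
  topP <- top_snp_vs_region(rhP, gwP, gP$geno)
  expect_true(mean(topP$pairs$ratio) < mean(top$pairs$ratio))
  expect_true(all(topP$pairs$ratio < 1))
})
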