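test_that("Welch t test closed forms and symmetry", {
  x <- c(1, 2, 3, 4)
  r <- welch_t(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # large-sample z approximation: means 0 vs 1, sd 1, n = 1e4
  set.seed(1)
  a <- rnorm(1e4); b <- rnorm(1e4, 1)
  expect_lt(welch_t(a, b)$p, 1e-100)
  # swapping groups negates t, preserves p
  r1 <- welch_t(a, b); r2 <- welch_t(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  # hand-computed Welch statistic
  y <- c(2, 4, 6, 8, 10)
  r3 <- welch_t(x, y)
  tm <- (mean(x) - mean(y)) / sqrt(var(x) / 4 + var(y) / 5)
  expect_equal(r3$t, tm, tolerance = 1e-10)
  # constant groups
  expect_equal(welch_t(c(1, 1), c(1, 1))$p, 1)
  expect_equal(welch_t(c(1, 1), c(2, 2))$p, 0)
})

test_that("KS test matches the brute-force ECDF oracle", {
  expect_equal(ks_2samp(1:20, 1:20)$D, 0)
  expect_equal(ks_2samp(1:10, 101:110)$D, 1)
  set.seed(2)
  for (k in 1:50) {
    x <- rnorm(sample(10:40, 1))
    y <- rnorm(sample(10:40, 1), sd = runif(1, 0.5, 2))
    expect_equal(ks_2samp(x, y)$D, ks_D_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("two-proportion test mirrors prop.test and is symmetric", {
  r <- two_prop_test(30, 100, 30, 100)
  expect_equal(r$p, 1)
  expect_lt(two_prop_test(50, 100, 10, 100)$p, 1e-8)
  # pooled z by hand (no correction)
  r2 <- two_prop_test(50, 100, 10, 100, correct = FALSE)
  p_pool <- 60 / 200
  z <- (0.5 - 0.1) / sqrt(p_pool * (1 - p_pool) * (1 / 100 + 1 / 100))
  expect_equal(r2$statistic, z^2, tolerance = 1e-10)
  # symmetric in the groups
  expect_equal(two_prop_test(40, 90, 20, 80)$p, two_prop_test(20, 80, 40, 90)$p)
  expect_error(two_prop_test(5, 3, 1, 10), "exceed")
})

make_site_stats <- function(n_per, h2_sea = 0.4, h2_island = 0.1, seed = 5) {
  set.seed(seed)
  grid <- expand.grid(density = c("island", "sea"),
                      genic = c("tss_expressed", "tss_not_expressed",
                                "intragenic", "intergenic"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    h2 <- if (grid$density[k] == "sea") h2_sea else h2_island
    hit <- runif(n_per) < h2   # treat h2 as the chance of being heritable
    data.frame(
      site_id = sprintf("cg_%s_%s_%03d", grid$density[k], grid$genic[k],
                        seq_len(n_per)),
      mean_m = rnorm(n_per, ifelse(grid$density[k] == "sea", 1.5, -2.7)),
      resid_var = rchisq(n_per, 3) / 15,
      h2 = ifelse(hit, pmin(runif(n_per, 0.1, 0.6), 0.95), 0),
      p = ifelse(hit, runif(n_per, 0, 0.049), runif(n_per, 0.05, 1)),
      sigma_g2 = ifelse(hit, runif(n_per, 0.05, 0.3), 0),
      density = grid$density[k], genic = grid$genic[k],
      stringsAsFactors = FALSE
    )
  }))
  out
}

test_that("context summaries report the eight groups and their tests", {
  ss <- make_site_stats(100)
  cs <- context_summaries(ss)
  expect_equal(nrow(cs$groups), 8)
  expect_equal(sum(cs$groups$n_sites), 800)
  expect_true(all(cs$groups$prop_heritable >= 0 & cs$groups$prop_heritable <= 1))
  # higher heritable proportion in sea than island is detected
  sea <- grepl("^sea", cs$groups$group)
  expect_gt(mean(cs$groups$prop_heritable[sea]),
            mean(cs$groups$prop_heritable[!sea]))
  pw <- cs$pairwise
  expect_equal(nrow(pw), choose(8, 2))
  # island vs sea proportion test significant under this separation
  row <- pw[pw$group1 == "island.intragenic" & pw$group2 == "sea.intragenic", ]
  expect_lt(row$prop_p, 0.05)
  # mean M separation island vs sea
  expect_lt(row$welch_p_mean, 1e-10)
  # pairwise p symmetric by construction (unordered pairs reported once)
  expect_true(all(pw$group1 != pw$group2))
  # 4-point correlations present for both density classes
  expect_equal(cs$prop_vs_genvar$density, c("island", "sea"))
  # identical values everywhere -> all pairwise p = 1
  ss2 <- ss
  ss2$mean_m <- 1; ss2$resid_var <- 0.2
  ss2$p <- 0.5; ss2$h2 <- 0; ss2$sigma_g2 <- 0
  cs2 <- context_summaries(ss2)
  expect_true(all(cs2$pairwise$welch_p_mean == 1))
  expect_true(all(cs2$pairwise$prop_p == 1))
})

test_that("summaries are invariant to site order", {
  ss <- make_site_stats(40)
  cs1 <- context_summaries(ss)
  cs2 <- context_summaries(ss[sample(nrow(ss)), ])
  expect_equal(cs1$groups, cs2$groups)
})

test_that("h2 regressions on window size, residual variance and context", {
  set.seed(7)
  n <- 400
  rh <- data.frame(site_id = sprintf("cg%04d", 1:n),
                   n_snps = sample(100:3000, n, TRUE),
                   p = runif(n, 0, 0.049))
  rv <- setNames(runif(n, 0.05, 0.5), rh$site_id)
  ctx <- setNames(sample(c("island", "sea"), n, TRUE), rh$site_id)
  # h2 depends on residual variance and context, not on SNP count
  rh$h2 <- 0.1 + 0.6 * rv[rh$site_id] + 0.1 * (ctx[rh$site_id] == "sea") +
    rnorm(n, 0, 0.03)
  part <- h2_variance_partition(rh, rv, ctx)
  expect_lt(abs(part$snp_count$slope), 1e-4)
  expect_gt(part$snp_count$p, 1e-4)       # null slope not wildly significant
  expect_gt(part$resid_var$r2, 0.4)
  expect_lt(part$context_anova$p, 0.05)
  # prediction helper: slope times SNP count
  expect_equal(predict_h2_increase(2.372e-5, 304), 2.372e-5 * 304)
  # fewer than 3 significant sites -> sentinel
  rh2 <- rh[1:2, ]
  expect_null(h2_variance_partition(rh2, rv, ctx))
})

test_that("risk-region comparison respects the inclusive boundary", {
  rh <- data.frame(site_id = c("a", "b", "c", "d"),
                   chrom = "chr1",
                   pos = c(1e6, 2e6, 2e6 + 1, 5e6),
                   h2 = c(0.3, 0.2, 0.4, 0.1),
                   p = c(0.01, 0.2, 0.01, 0.04))
  risk <- data.frame(chrom = "chr1", pos = 1e6, id = "rs1")
  out <- risk_region_compare(rh, risk)
  # site exactly 1 Mb away is within; 1 Mb + 1 is outwith
  expect_equal(out$within$n, 2)
  expect_equal(out$outwith$n, 2)
  # empty risk list -> all outwith
  out0 <- risk_region_compare(rh, risk[0, ])
  expect_equal(out0$within$n, 0)
  expect_equal(out0$outwith$n, 4)
  # regions covering everything -> outwith empty
  risk_all <- data.frame(chrom = "chr1", pos = c(1e6, 3e6, 5e6), id = letters[1:3])
  expect_equal(risk_region_compare(rh, risk_all)$outwith$n, 0)
})
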