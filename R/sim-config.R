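#' Simulation configuration
#'
#' Parameters for the synthetic genotype/annotation/methylation generator.
#' Defaults emulate the study design the analysis is built for: 132 unrelated
#' samples, a single chromosome, roughly 300 SNPs per +/-1 Mb window, and a
#' contextual mix of sites proportional to the island/sea by genic-context
#' composition of a 450K-style array.
#'
#' @param n_samples number of individuals (default 132).
#' @param chrom chromosome name of the simulated contig.
#' @param chrom_length contig length in bp.
#' @param snp_density SNPs per bp (default 1.5e-4, i.e. 300 SNPs per 2 Mb
#'   window).
#' @param maf_range interval in (0, 0.5] from which per-SNP allele
#'   frequencies are drawn uniformly.
#' @param ld_rho adjacent-SNP haplotype copying probability in [0, 1);
#'   first-order autoregressive LD.
#' @param n_sites number of CpG sites to simulate.
#' @param context_mix named numeric vector of proportions over the eight
#'   contextual groups, names `<density>.<genic>` with density in
#'   `{island, sea}` and genic in `{tss_expressed, tss_not_expressed,
#'   intragenic, intergenic}`; must sum to 1.
#' @param h2_dist distribution of true local heritability per site: either
#'   `list(type = "point", value = h2)` or
#'   `list(type = "beta", shape1 =, shape2 =)` (draws in [0, 1)).
#' @param n_causal_per_site causal SNPs per site, drawn from the site's
#'   +/-1 Mb window (reduced with a warning if the window is smaller).
#' @param covariate_effects named vector of fixed-effect sizes on the
#'   M-value scale: `sex`, `age` (per year, age centred at 55), `batch`,
#'   `side`, `diagnosis`.
#' @param missing_rate genotype missingness rate (default 0, no missing
#'   calls).
#' @param n_genes number of gene models in the simulated annotation.
#' @param n_islands_intergenic stand-alone CpG islands placed between genes.
#' @param sigma_e2 residual (non-genetic, non-covariate) variance of the
#'   M-value, in M-units squared.
#' @param seed integer random seed (mandatory).
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 132,
                       chrom = "chr1",
                       chrom_length = 5e6,
                       snp_density = 1.5e-4,
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0.2,
                       n_sites = 200,
                       context_mix = default_context_mix(),
                       h2_dist = list(type = "point", value = 0.3),
                       n_causal_per_site = 5,
                       covariate_effects = c(sex = 0.1, age = 0.005,
                                             batch = 0.2, side = 0.1,
                                             diagnosis = 0),
                       missing_rate = 0,
                       n_genes = 60,
                       n_islands_intergenic = 10,
                       sigma_e2 = 1,
                       seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("`seed` is mandatory and must be a single integer")
  if (n_samples < 2) stopf("`n_samples` must be at least 2")
  if (chrom_length <= 1e4) stopf("`chrom_length` must exceed 10 kb")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stopf("`maf_range` must be an interval within (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stopf("`ld_rho` must lie in [0, 1)")
  cm <- context_mix
  if (is.null(names(cm)) || abs(sum(cm) - 1) > 1e-8 || any(cm < 0))
    stopf("`context_mix` must be a named vector of non-negative proportions summing to 1")
  ok_names <- as.vector(outer(c("island", "sea"), GENIC_LEVELS, paste, sep = "."))
  if (!all(names(cm) %in% ok_names))
    stopf("`context_mix` names must be of the form density.genic, e.g. 'island.tss_expressed'")
  tss_mass <- sum(cm[grepl("tss|intragenic", names(cm))])
  if (n_genes == 0 && tss_mass > 0)
    stopf("degenerate config: context_mix places mass on genic contexts but n_genes = 0")
  if (!h2_dist$type %in% c("point", "beta"))
    stopf("`h2_dist$type` must be 'point' or 'beta'")
  if (h2_dist$type == "point" &&
      (h2_dist$value < 0 || h2_dist$value >= 1))
    stopf("point-mass h2 must lie in [0, 1)")
  structure(list(
    n_samples = as.integer(n_samples), chrom = chrom,
    chrom_length = as.integer(chrom_length), snp_density = snp_density,
    maf_range = maf_range, ld_rho = ld_rho, n_sites = as.integer(n_sites),
    context_mix = cm, h2_dist = h2_dist,
    n_causal_per_site = as.integer(n_causal_per_site),
    covariate_effects = covariate_effects, missing_rate = missing_rate,
    n_genes = as.integer(n_genes),
    n_islands_intergenic = as.integer(n_islands_intergenic),
    sigma_e2 = sigma_e2, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default contextual mix of simulated CpG sites
#'
#' Proportions over the eight island/sea by genic-context groups, modelled
#' on the composition of autosomal 450K sites restricted to the two extreme
#' CpG-density classes (islands and open sea).
#' @return Named numeric vector summing to 1.
#' @export
default_context_mix <- function() {
  # counts patterned on a 450K-style composition (island, sea) x
  # (tss_expressed, tss_not_expressed, intragenic, intergenic)
  counts <- c(
    island.tss_expressed = 13838, island.tss_not_expressed = 19052,
    island.intragenic = 31356, island.intergenic = 10028,
    sea.tss_expressed = 2074, sea.tss_not_expressed = 7603,
    sea.intragenic = 30106, sea.intergenic = 17634
  )
  counts / sum(counts)
}

draw_h2 <- function(h2_dist, n) {
  if (h2_dist$type == "point") rep(h2_dist$value, n)
  else pmin(rbeta(n, h2_dist$shape1, h2_dist$shape2), 1 - 1e-9)
}
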