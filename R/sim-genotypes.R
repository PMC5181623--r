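#' Simulate genotypes under Hardy-Weinberg with first-order LD
#'
#' Draws per-SNP allele frequencies uniformly from `maf_range`, then builds
#' two haplotypes per individual by a first-order autoregressive copying
#' process: the allele at SNP *j* copies the allele at SNP *j-1* with
#' probability `ld_rho` and is otherwise drawn fresh as Bernoulli(p_j).
#' Dosages are the sum of the two haplotypes, so single-SNP genotypes are
#' in Hardy-Weinberg proportions while adjacent SNPs are correlated.
#'
#' @param config a [sim_config()] object; uses `n_samples`, `chrom`,
#'   `chrom_length`, `snp_density`, `maf_range`, `ld_rho`, `missing_rate`.
#' @param n_snps optional explicit SNP count (overrides
#'   `snp_density * chrom_length`).
#' @return list with `geno` (a [genotype_data()]) and `true_freq`
#'   (numeric vector of the generating alternate-allele frequencies).
#' @export
sim_genotypes <- function(config, n_snps = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$ld_rho >= 1) stopf("ld_rho must be < 1")
  set.seed(config$seed + 2L)
  sim_genotypes_impl(config, n_snps)
}

# internal worker, does not touch the RNG seed (callers manage it)
sim_genotypes_impl <- function(config, n_snps = NULL) {
  n <- config$n_samples
  L <- config$chrom_length
  m <- if (is.null(n_snps)) max(1L, as.integer(round(config$snp_density * L)))
       else as.integer(n_snps)
  pos <- sort(sample.int(L, m))
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  rho <- config$ld_rho

  nh <- 2L * n
  hap <- matrix(0L, nh, m)
  hap[, 1] <- rbinom(nh, 1L, p[1])
  if (m > 1) {
    for (j in 2:m) {
      copy <- runif(nh) < rho
      fresh <- rbinom(nh, 1L, p[j])
      hap[, j] <- ifelse(copy, hap[, j - 1L], fresh)
    }
  }
  dos <- hap[seq(1L, nh, by = 2L), , drop = FALSE] +
         hap[seq(2L, nh, by = 2L), , drop = FALSE]
  storage.mode(dos) <- "double"
  if (config$missing_rate > 0)
    dos[runif(length(dos)) < config$missing_rate] <- NA_real_
  rownames(dos) <- sprintf("s%04d", seq_len(n))
  snps <- data.frame(chrom = config$chrom, pos = pos,
                     id = sprintf("snp%05d", seq_len(m)),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  list(geno = genotype_data(dos, snps), true_freq = p)
}
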