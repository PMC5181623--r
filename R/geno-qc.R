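#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test of Hardy-Weinberg proportions.  Given
#' the allele counts, heterozygote counts follow a known conditional
#' distribution; the p-value is the sum of the probabilities of all
#' heterozygote counts no more probable than the observed one.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (non-negative; total
#'   must be positive).
#' @return p-value in (0, 1]; monomorphic input returns 1.
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n <= 0) stopf("total genotype count must be positive")
  na <- 2 * n_hom_ref + n_het   # count of the "ref" allele
  nb <- 2 * n_hom_alt + n_het
  if (na == 0 || nb == 0) return(1)
  nr <- min(na, nb)             # rarer allele count
  hets <- seq(nr %% 2, nr, by = 2)
  # log P(h | n, nr) up to a common constant:
  #   P(h) propto n! / (n1! h! n2!) * 2^h  with n1 = (nr - h)/2 rare
  #   homozygotes and n2 = n - h - n1
  n1 <- (nr - hets) / 2
  n2 <- n - hets - n1
  logp <- hets * log(2) - lgamma(n1 + 1) - lgamma(hets + 1) - lgamma(n2 + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  if (is.na(obs)) stopf("heterozygote count incompatible with allele counts")
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

#' Remove samples with excessive genotype missingness
#'
#' @param geno a [genotype_data()].
#' @param max_missing maximum tolerated fraction of missing SNP calls per
#'   sample (default 0.05; a sample with strictly more than 5% missing is
#'   excluded).
#' @return list with `geno` (filtered) and `report` (data.frame of removed
#'   samples with their missing fractions).
#' @export
filter_sample_callrate <- function(geno, max_missing = 0.05) {
  stopifnot(inherits(geno, "genotype_data"))
  if (length(geno$dosage) == 0L) stopf("empty dosage matrix")
  miss <- rowMeans(is.na(geno$dosage))
  drop <- miss > max_missing
  if (all(drop)) stopf("all samples exceed the missingness threshold")
  report <- data.frame(sample_id = rownames(geno$dosage)[drop],
                       missing_frac = miss[drop], row.names = NULL)
  list(geno = subset_geno(geno, samples = !drop), report = report)
}

snp_genotype_counts <- function(g) {
  c(hom_ref = sum(g == 0, na.rm = TRUE),
    het = sum(g == 1, na.rm = TRUE),
    hom_alt = sum(g == 2, na.rm = TRUE))
}

#' Apply the four successive SNP quality-control filters
#'
#' Filters are applied in order, each to the survivors of the previous one:
#' (i) call rate (missing in more than `max_missing` of samples), (ii)
#' exact Hardy-Weinberg equilibrium (`p < hwe_p`), (iii) minor allele
#' frequency (`MAF < maf_min`), and (iv) differential missingness between
#' cases and controls (two-sided two-proportion test, `p < diffmiss_p`;
#' skipped with a message when no labels are supplied).  Allele frequencies
#' use non-missing calls only.
#'
#' @param geno a [genotype_data()] (sample filtering should be done first;
#'   see [filter_sample_callrate()]).
#' @param cc_labels optional per-sample case/control labels (2 levels),
#'   aligned with the rows of the dosage matrix.
#' @param max_missing,hwe_p,maf_min,diffmiss_p thresholds; defaults 0.05,
#'   1e-4, 0.01, 1e-5.
#' @return list with `geno` (filtered) and `report` (data.frame: filter
#'   name, threshold, number removed, comma-separated removed ids).
#' @export
filter_snps <- function(geno, cc_labels = NULL, max_missing = 0.05,
                        hwe_p = 1e-4, maf_min = 0.01, diffmiss_p = 1e-5) {
  stopifnot(inherits(geno, "genotype_data"))
  d <- geno$dosage
  alive <- rep(TRUE, ncol(d))
  removed <- list()

  # (i) SNP call rate
  miss <- colMeans(is.na(d))
  r1 <- alive & miss > max_missing
  removed$callrate <- colnames(d)[r1]; alive <- alive & !r1

  # (ii) exact HWE
  r2 <- rep(FALSE, ncol(d))
  for (j in which(alive)) {
    cnt <- snp_genotype_counts(d[, j])
    if (sum(cnt) == 0) next
    r2[j] <- hwe_exact_p(cnt[1], cnt[2], cnt[3]) < hwe_p
  }
  removed$hwe <- colnames(d)[r2]; alive <- alive & !r2

  # (iii) MAF
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  r3 <- alive & (is.na(maf) | maf < maf_min)
  removed$maf <- colnames(d)[r3]; alive <- alive & !r3

  # (iv) differential missingness
  if (is.null(cc_labels)) {
    msgf("no case/control labels supplied; differential-missingness filter skipped")
    removed$diffmiss <- character(0)
  } else {
    lab <- as.factor(cc_labels)
    if (nlevels(lab) != 2L) stopf("cc_labels must have exactly two levels")
    g1 <- lab == levels(lab)[1]
    r4 <- rep(FALSE, ncol(d))
    for (j in which(alive)) {
      k1 <- sum(is.na(d[g1, j])); n1 <- sum(g1)
      k2 <- sum(is.na(d[!g1, j])); n2 <- sum(!g1)
      if (k1 + k2 == 0) next
      r4[j] <- two_prop_test(k1, n1, k2, n2)$p < diffmiss_p
    }
    removed$diffmiss <- colnames(d)[r4]; alive <- alive & !r4
  }

  thresholds <- c(callrate = max_missing, hwe = hwe_p, maf = maf_min,
                  diffmiss = diffmiss_p)
  report <- data.frame(
    filter = names(removed),
    threshold = thresholds[names(removed)],
    n_removed = vapply(removed, length, integer(1)),
    removed_ids = vapply(removed, paste, character(1), collapse = ","),
    row.names = NULL
  )
  list(geno = subset_geno(geno, snps = alive), report = report)
}

#' X-chromosome inbreeding coefficient and sex-consistency flags
#'
#' Per sample, `F = 1 - O(het) / E(het)` with the expected heterozygosity
#' `E(het) = sum 2 p (1 - p)` accumulated over the SNPs non-missing in that
#' sample (allele frequencies estimated from all non-missing calls).
#' Recorded females with `F > f_female` (default 0.98, more inbred than
#' expected) and recorded males with `F < f_male` (default 0.2, less inbred
#' than expected) are flagged for removal.
#'
#' @param x_geno a [genotype_data()] restricted to X-chromosome SNPs.
#' @param sex character/factor of recorded sex per sample (`"F"`/`"M"`).
#' @param f_female,f_male flag thresholds.
#' @return data.frame: `sample_id, sex, o_het, e_het, F, flag` where `flag`
#'   is one of `ok`, `remove`, `unevaluable`.
#' @export
x_inbreeding_f <- function(x_geno, sex, f_female = 0.98, f_male = 0.2) {
  stopifnot(inherits(x_geno, "genotype_data"))
  d <- x_geno$dosage
  sex <- as.character(sex)
  stopifnot(length(sex) == nrow(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < 50)
    warnf("only %d polymorphic X SNPs; inbreeding estimates will be noisy", sum(poly))
  ehet_snp <- 2 * p * (1 - p)
  n <- nrow(d)
  o_het <- e_het <- Fhat <- numeric(n)
  flag <- character(n)
  for (i in seq_len(n)) {
    ok <- !is.na(d[i, ])
    o_het[i] <- sum(d[i, ok] == 1)
    e_het[i] <- sum(ehet_snp[ok])
    if (e_het[i] <= 0) {
      Fhat[i] <- NA_real_; flag[i] <- "unevaluable"
    } else {
      Fhat[i] <- 1 - o_het[i] / e_het[i]
      flag[i] <- if ((sex[i] == "F" && Fhat[i] > f_female) ||
                     (sex[i] == "M" && Fhat[i] < f_male)) "remove" else "ok"
    }
  }
  data.frame(sample_id = rownames(d), sex = sex, o_het = o_het,
             e_het = e_het, F = Fhat, flag = flag, row.names = NULL)
}

#' Genotype principal components
#'
#' Singular value decomposition of the column-standardized dosage matrix
#' (missing dosages mean-imputed inside the standardization only).  Scores
#' are `U %*% diag(d)` restricted to the first `k` components, with a
#' deterministic sign convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param geno a [genotype_data()].
#' @param k number of components.
#' @return samples x k matrix of scores (columns `PC1`..`PCk`).
#' @export
genotype_pcs <- function(geno, k) {
  stopifnot(inherits(geno, "genotype_data"))
  n <- nrow(geno$dosage)
  if (k == 0) return(matrix(numeric(0), n, 0,
                            dimnames = list(rownames(geno$dosage), NULL)))
  if (n < k + 1) stopf("need at least k + 1 samples")
  Z <- geno$dosage
  mu <- colMeans(Z, na.rm = TRUE)
  for (j in seq_len(ncol(Z))) Z[is.na(Z[, j]), j] <- mu[j]
  s <- apply(Z, 2, sd)
  keep <- s > 0
  Z <- scale(Z[, keep, drop = FALSE])
  sv <- svd(Z, nu = min(n, sum(keep)), nv = min(n, sum(keep)))
  rank <- sum(sv$d > sv$d[1] * 1e-8)
  if (k > rank) stopf("k = %d exceeds the rank (%d) of the genotype matrix", k, rank)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip, `*`)
  dimnames(scores) <- list(rownames(geno$dosage), paste0("PC", seq_len(k)))
  scores
}
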