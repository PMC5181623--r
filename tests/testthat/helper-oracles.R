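# Independent oracles used by the test suite.  Each deliberately takes a
# different computational route from the package implementation.

# Exact HWE: conditional probability of each heterozygote count by the
# upward recurrence P(h+2)/P(h) = 4 n1 n2 / ((h+1)(h+2)), then normalize.
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  na <- 2 * n_hom_ref + n_het
  nb <- 2 * n_hom_alt + n_het
  if (na == 0 || nb == 0) return(1)
  nr <- min(na, nb)
  hets <- seq(nr %% 2, nr, by = 2)
  pr <- numeric(length(hets))
  pr[1] <- 1
  if (length(hets) > 1) {
    for (k in 1:(length(hets) - 1)) {
      h <- hets[k]
      n1 <- (nr - h) / 2            # rare homozygotes at h
      n2 <- n - h - n1
      pr[k + 1] <- pr[k] * 4 * n1 * n2 / ((h + 1) * (h + 2))
    }
  }
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

# Restricted log-likelihood of y ~ N(X b, h2 A + (1-h2) I) with the total
# variance profiled out, computed the textbook way via Cholesky of the
# full covariance (no eigendecomposition, no transformed coordinates).
reml_ll_direct <- function(h2, y, X, A) {
  n <- length(y); p <- ncol(X)
  V <- h2 * A + (1 - h2) * diag(n)
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  My <- backsolve(L, y, transpose = TRUE)
  MX <- backsolve(L, X, transpose = TRUE)
  XtViX <- crossprod(MX)
  beta <- solve(XtViX, crossprod(MX, My))
  r <- My - MX %*% beta
  sig2 <- sum(r^2) / (n - p)
  if (sig2 <= 0) return(-Inf)
  as.numeric(-0.5 * ((n - p) * log(2 * pi * sig2) + 2 * sum(log(diag(L))) +
            determinant(XtViX, logarithm = TRUE)$modulus + (n - p)))
}

# dense grid-search REML oracle: argmax of the direct restricted
# likelihood over a 1e4-point h2 grid
reml_grid_oracle <- function(y, X, A, npts = 1e4) {
  grid <- seq(0, 1 - 1e-6, length.out = npts)
  ll <- vapply(grid, function(h2) reml_ll_direct(h2, y, X, A), numeric(1))
  grid[which.max(ll)]
}

# per-pair GRM formula oracle: A_ij = sum_k w_ik w_jk / N with the
# VanRaden standardization recomputed from scratch
grm_pair_oracle <- function(dosage) {
  p <- colMeans(dosage, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  d <- dosage[, keep, drop = FALSE]
  p <- p[keep]
  n <- nrow(d); N <- ncol(d)
  W <- matrix(0, n, N)
  for (k in seq_len(N)) {
    g <- d[, k]
    g[is.na(g)] <- 2 * p[k]
    W[, k] <- (g - 2 * p[k]) / sqrt(2 * p[k] * (1 - p[k]))
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    A[i, j] <- sum(W[i, ] * W[j, ]) / N
  A
}

# brute-force two-sample KS statistic: max gap between the two ECDFs
ks_D_oracle <- function(x, y) {
  z <- sort(unique(c(x, y)))
  max(abs(vapply(z, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# small genotype fixture: n samples x m SNPs at given frequencies,
# positions 1..m * spacing
make_geno <- function(n, freqs, spacing = 1000L, chrom = "chr1", seed = 1) {
  set.seed(seed)
  m <- length(freqs)
  d <- vapply(freqs, function(p) rbinom(n, 2, p), numeric(n))
  rownames(d) <- sprintf("s%04d", seq_len(n))
  genotype_data(d, data.frame(chrom = chrom, pos = seq_len(m) * spacing,
                              id = sprintf("snp%05d", seq_len(m)),
                              ref = "A", alt = "G"))
}
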