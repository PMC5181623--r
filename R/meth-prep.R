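#' Beta-value to M-value transformation (and back)
#'
#' `M = log2(beta / (1 - beta))`: an M-value of 0 corresponds to 50%
#' methylation, positive M to > 50%, negative to < 50%.  Betas are clipped
#' to `[eps, 1 - eps]` before the logit so the transform never produces
#' infinities.
#'
#' @param beta methylation proportions.
#' @param M M-values.
#' @param eps clipping constant (default 1e-6).
#' @return numeric vector of the same length.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(M) 1 / (1 + 2^(-M))

#' Filter CpG sites by detection p-values
#'
#' A site is retained iff the fraction of samples in which it was not
#' detected above background (detection `p >= p_thresh`) is at most
#' `max_fail_frac`.
#'
#' @param detp samples x sites matrix of detection p-values (column names
#'   are site ids).
#' @param p_thresh detection threshold (default 0.01).
#' @param max_fail_frac maximum tolerated failing-sample fraction
#'   (default 0.05).
#' @return character vector of retained site ids (or column indices when
#'   unnamed).
#' @export
detection_filter_sites <- function(detp, p_thresh = 0.01, max_fail_frac = 0.05) {
  detp <- as.matrix(detp)
  fail <- colMeans(detp >= p_thresh)
  keep <- fail <= max_fail_frac
  if (!is.null(colnames(detp))) colnames(detp)[keep] else which(keep)
}

#' Remove listed CpG sites (and optionally non-autosomal sites)
#'
#' Consumes an exclusion list (e.g. published cross-reactive or
#' SNP-overlapping probes); ids absent from the data are ignored with a
#' logged count.
#'
#' @param meth a [methylation_data()].
#' @param exclude_ids character vector of site ids to drop.
#' @param autosomes_only drop sites on chrX/chrY/X/Y as well.
#' @return filtered [methylation_data()].
#' @export
exclusion_filter <- function(meth, exclude_ids = character(0),
                             autosomes_only = FALSE) {
  stopifnot(inherits(meth, "methylation_data"))
  ids <- meth$sites$id
  unknown <- setdiff(exclude_ids, ids)
  if (length(unknown))
    msgf("%d exclusion ids not present in the data; ignored", length(unknown))
  keep <- !(ids %in% exclude_ids)
  if (autosomes_only)
    keep <- keep & !(meth$sites$chrom %in% c("chrX", "chrY", "X", "Y"))
  if (!any(keep)) warnf("exclusion removed every site")
  subset_meth(meth, sites = keep)
}

# covariate table -> design matrix (intercept + indicator contrasts),
# with aliased columns dropped via pivoted QR
build_design <- function(covars) {
  df <- covars[, setdiff(names(covars), "sample_id"), drop = FALSE]
  X <- model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    warnf("design rank-deficient; dropping aliased columns: %s",
          paste(drop, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  X
}

#' Residualize methylation on covariates
#'
#' Per-site ordinary least squares of the M-values on the covariate design
#' (categorical covariates expanded to indicator contrasts), returning the
#' residual methylation matrix and the per-site residual variance with an
#' unbiased `n - rank` denominator.
#'
#' @param meth a [methylation_data()] on the M scale.
#' @param covars covariate data.frame aligned with the samples (a
#'   `sample_id` column, if present, is checked against the row names and
#'   not modeled); include genotype PC scores as numeric columns.
#' @return list with `meth` (residualized [methylation_data()]) and
#'   `resid_var` (named numeric, one entry per site).
#' @export
residualize <- function(meth, covars) {
  stopifnot(inherits(meth, "methylation_data"))
  if (meth$scale != "M") stopf("residualize expects M-values; use beta_to_m() first")
  Y <- meth$values
  n <- nrow(Y)
  stopifnot(nrow(covars) == n)
  if (!is.null(covars$sample_id) && !is.null(rownames(Y)) &&
      !identical(as.character(covars$sample_id), rownames(Y)))
    stopf("covariate sample ids do not match the methylation samples")
  if (any(!complete.cases(covars))) stopf("covariate rows must be complete")
  X <- build_design(covars)
  if (n <= ncol(X)) stopf("need more samples than model columns")
  qrX <- qr(X)
  res <- qr.resid(qrX, Y)
  rv <- colSums(res^2) / (n - qrX$rank)
  out <- meth
  out$values <- res
  list(meth = out, resid_var = setNames(rv, meth$sites$id))
}
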