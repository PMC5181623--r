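#' Genotype container
#'
#' Holds a sample-by-SNP allele-dosage matrix (counts of the alternate
#' allele: 0, 1, 2 or `NA` for a missing call) together with the SNP map.
#'
#' @param dosage numeric matrix, samples in rows (rownames = sample ids),
#'   SNPs in columns (colnames = SNP ids); entries in `{0, 1, 2, NA}`.
#' @param snps data.frame with columns `chrom`, `pos` (1-based bp), `id`,
#'   `ref`, `alt`; one row per column of `dosage`, positions strictly
#'   increasing within each chromosome.
#' @return An object of class `genotype_data`.
#' @export
genotype_data <- function(dosage, snps) {
  dosage <- as.matrix(dosage)
  stopifnot(is.data.frame(snps), nrow(snps) == ncol(dosage))
  req <- c("chrom", "pos", "id")
  if (!all(req %in% names(snps))) stopf("`snps` needs columns %s", paste(req, collapse = ", "))
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    stopf("dosages must be 0, 1, 2 or NA")
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stopf("SNP positions must be strictly increasing within chromosome %s", ch)
  }
  if (is.null(snps$ref)) snps$ref <- "A"
  if (is.null(snps$alt)) snps$alt <- "G"
  colnames(dosage) <- snps$id
  structure(list(dosage = dosage, snps = snps), class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("genotype_data: %d samples x %d SNPs (%s)\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(unique(x$snps$chrom), collapse = ",")))
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$dosage)

# subset helper (samples, snps by logical/index)
subset_geno <- function(geno, samples = NULL, snps = NULL) {
  d <- geno$dosage
  s <- geno$snps
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (!is.null(snps)) {
    d <- d[, snps, drop = FALSE]
    s <- s[snps, , drop = FALSE]
    rownames(s) <- NULL
  }
  structure(list(dosage = d, snps = s), class = "genotype_data")
}

#' Methylation container
#'
#' Sample-by-site methylation value matrix with the site map and a scale
#' tag.  Values are either beta (proportions in (0,1)) or M-values
#' (`log2(beta/(1-beta))`).
#'
#' @param values numeric matrix, samples in rows, CpG sites in columns
#'   (colnames = site ids).
#' @param sites data.frame with columns `chrom`, `pos` (1-based bp of the
#'   CpG cytosine) and `id`.
#' @param scale `"M"` or `"beta"`.
#' @return An object of class `methylation_data`.
#' @export
methylation_data <- function(values, sites, scale = c("M", "beta")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  stopifnot(is.data.frame(sites), nrow(sites) == ncol(values))
  if (scale == "beta") {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) <= 0 || max(v) >= 1))
      stopf("beta values must lie strictly inside (0, 1); clip or transform first")
  } else if (any(!is.finite(values))) {
    stopf("M-values must be finite")
  }
  colnames(values) <- sites$id
  structure(list(values = values, sites = sites, scale = scale),
            class = "methylation_data")
}

#' @export
print.methylation_data <- function(x, ...) {
  cat(sprintf("methylation_data: %d samples x %d sites, %s scale\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.methylation_data <- function(x) dim(x$values)

subset_meth <- function(meth, samples = NULL, sites = NULL) {
  v <- meth$values
  s <- meth$sites
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(sites)) {
    v <- v[, sites, drop = FALSE]
    s <- s[sites, , drop = FALSE]
    rownames(s) <- NULL
  }
  structure(list(values = v, sites = s, scale = meth$scale),
            class = "methylation_data")
}
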