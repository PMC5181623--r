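# File-format readers and writers.  Internal conventions: 1-based point
# positions (VCF-style), 0-based half-open intervals (BED-style);
# conversions happen here and nowhere else.

#' Read genotypes from a VCF file
#'
#' Parses the GT field of a diploid VCF 4.x (via vcfR) into alternate
#' allele dosages; `.` alleles give a missing call.  Multi-allelic records
#' are skipped with a logged count.
#'
#' @param path VCF file (plain or gzipped).
#' @return a [genotype_data()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    msgf("skipping %d multi-allelic records", sum(multi))
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  a1 <- sub("^([0-9.]+)[/|].*$", "\\1", gt)
  a2 <- sub("^[0-9.]+[/|]([0-9.]+)$", "\\1", gt)
  dose <- suppressWarnings(as.numeric(a1 == "1") + as.numeric(a2 == "1"))
  dose[a1 == "." | a2 == "." | is.na(gt)] <- NA_real_
  d <- matrix(dose, nrow = nrow(gt), dimnames = dimnames(gt))
  snps <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     id = fix$ID, ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  noid <- is.na(snps$id) | snps$id == "."
  snps$id[noid] <- sprintf("%s:%d", snps$chrom[noid], snps$pos[noid])
  genotype_data(t(d), snps)
}

#' Write genotypes to a VCF file
#'
#' Plain-text VCF 4.2 with a GT-only FORMAT; missing dosages become `./.`.
#' Round-trips through [read_vcf()] exactly.
#'
#' @param geno a [genotype_data()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_data"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", unique(geno$snps$chrom)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(geno$dosage)),
                     collapse = "\t")), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(ncol(geno$dosage))) {
    g <- geno$dosage[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    writeLines(paste(c(geno$snps$chrom[j], geno$snps$pos[j], geno$snps$id[j],
                       geno$snps$ref[j], geno$snps$alt[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write BED interval files
#'
#' BED is 0-based half-open; so is the internal interval representation,
#' hence no shifting beyond what [rtracklayer::import()] performs.
#'
#' @param path file path.
#' @return `read_bed`: data.frame `chrom, start, end, name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomeInfoDb_seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             name = if (!is.null(gr$name)) gr$name else
               sprintf("iv%04d", seq_along(gr)),
             stringsAsFactors = FALSE)
}

# small indirection so the import is explicit and testable
GenomeInfoDb_seqnames <- function(gr) GenomicRanges::seqnames(gr)

#' @rdname read_bed
#' @param intervals data.frame `chrom, start, end` (+ optional `name`).
#' @export
write_bed <- function(intervals, path) {
  df <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  cols <- c("chrom", "start", "end")
  if (!is.null(df$name)) cols <- c(cols, "name")
  write.table(df[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a TSV matrix (rows = features, columns = samples)
#'
#' The first column holds feature ids; remaining column names are sample
#' ids.  Writers are deterministic: fixed `%.6g` float format, features in
#' input order.
#'
#' @param path file path.
#' @return `read_tsv_matrix`: numeric matrix with feature rownames.
#' @export
read_tsv_matrix <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (ncol(dt) < 1L) stopf("empty TSV: %s", path)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' @rdname read_tsv_matrix
#' @param m numeric matrix (features x samples).
#' @param id_col name for the feature-id column.
#' @export
write_tsv_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), formatC(m, format = "g", digits = 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(m))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write a methylation TSV (sites as rows)
#'
#' Layout: `site_id, chrom, pos`, then one column per sample.
#'
#' @param path file path.
#' @param scale `"M"` or `"beta"`.
#' @return `read_methylation_tsv`: a [methylation_data()].
#' @export
read_methylation_tsv <- function(path, scale = c("M", "beta")) {
  scale <- match.arg(scale)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("site_id", "chrom", "pos")
  if (!all(need %in% names(dt)))
    stopf("methylation TSV needs columns %s", paste(need, collapse = ", "))
  sites <- data.frame(chrom = dt$chrom, pos = as.integer(dt$pos),
                      id = dt$site_id, stringsAsFactors = FALSE)
  v <- t(as.matrix(dt[, setdiff(names(dt), need), drop = FALSE]))
  storage.mode(v) <- "double"
  colnames(v) <- sites$id
  methylation_data(v, sites, scale = scale)
}

#' @rdname read_methylation_tsv
#' @param meth a [methylation_data()].
#' @export
write_methylation_tsv <- function(meth, path) {
  v <- t(meth$values)
  df <- data.frame(site_id = meth$sites$id, chrom = meth$sites$chrom,
                   pos = meth$sites$pos,
                   formatC(v, format = "g", digits = 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-(1:3)] <- rownames(meth$values)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

write_tsv_df <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- formatC(df[[j]], format = "g", digits = 6)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
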