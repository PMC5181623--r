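#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()].  Either a [sim_config()]
#' is supplied (the pipeline simulates its own inputs and writes them
#' under `out_dir/inputs/`) or the `paths` list points at existing files:
#' `vcf`, `meth` (methylation TSV), `covar` (covariate TSV), optional
#' `islands` (BED), `genes` (gene-region TSV), `expressed` (one gene id
#' per line), `risk_snps` (TSV `chrom, pos, id`), `exclude` (one site id
#' per line).
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed recorded in the manifest (and used for
#'   simulation when `sim` is given).
#' @param sim optional [sim_config()].
#' @param paths named list of input paths (ignored when `sim` is given).
#' @param window regional window half-width in bp.
#' @param alpha nominal significance level.
#' @param thresholds GWAS thresholds.
#' @param covariate_mode `"fixed"` or `"residualized"` (REML covariate
#'   handling).
#' @param meth_scale scale of the methylation input (`"M"` or `"beta"`).
#' @param n_pcs genotype principal components added to the covariates.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed, sim = NULL, paths = list(),
                            window = 1e6, alpha = 0.05,
                            thresholds = c(5e-2, 5e-4, 5e-8),
                            covariate_mode = c("fixed", "residualized"),
                            meth_scale = c("M", "beta"), n_pcs = 2) {
  covariate_mode <- match.arg(covariate_mode)
  meth_scale <- match.arg(meth_scale)
  if (window <= 0) stopf("window must be positive")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (is.null(sim)) {
    req <- c("vcf", "meth", "covar")
    miss <- setdiff(req, names(paths))
    if (length(miss)) stopf("paths missing required inputs: %s", paste(miss, collapse = ", "))
    absent <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(absent)) stopf("input files not found: %s", paste(absent, collapse = ", "))
  } else stopifnot(inherits(sim, "sim_config"))
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 paths = paths, window = window, alpha = alpha,
                 thresholds = thresholds, covariate_mode = covariate_mode,
                 meth_scale = meth_scale, n_pcs = as.integer(n_pcs)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: genotype QC (sample call rate, then the four
#' successive SNP filters) -> genotype principal components -> methylation
#' preparation (beta-to-M if needed, exclusion list, residualization) ->
#' site annotation (CpG density + genic context) -> regional heritability
#' scan -> SNP-by-SNP GWAS on residuals -> contextual summaries, variance
#' partition and (if risk SNPs are given) risk-region comparison.  All
#' result tables are written as TSV under `out_dir`, along with a
#' `manifest.json` recording the seed, input digests and per-stage counts.
#' A stage failure aborts with the stage name in the message.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stopf("pipeline stage '%s' failed: %s",
                                       name, conditionMessage(e)))
  }
  manifest <- list(seed = config$seed, window = config$window,
                   alpha = config$alpha, stages = list())

  # ---- inputs -------------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- config$sim
    annot <- stage("simulate", sim_annotation(sim))
    gsim <- stage("simulate", sim_genotypes(sim))
    msim <- stage("simulate", sim_methylation(gsim$geno, annot, sim))
    geno <- gsim$geno; meth <- msim$meth; covars <- msim$covars
    indir <- file.path(config$out_dir, "inputs")
    dir.create(indir, showWarnings = FALSE)
    write_vcf(geno, file.path(indir, "genotypes.vcf"))
    write_methylation_tsv(meth, file.path(indir, "methylation.tsv"))
    write_tsv_df(covars, file.path(indir, "covariates.tsv"))
    write_bed(annot$islands, file.path(indir, "islands.bed"))
    write_tsv_df(annot$regions, file.path(indir, "gene_regions.tsv"))
    writeLines(annot$expressed$wcb, file.path(indir, "expressed_wcb.txt"))
    write_tsv_df(msim$truth, file.path(indir, "truth.tsv"))
    inputs <- list.files(indir, full.names = TRUE)
    risk <- NULL
  } else {
    p <- config$paths
    geno <- stage("read", read_vcf(p$vcf))
    meth <- stage("read", read_methylation_tsv(p$meth, scale = config$meth_scale))
    covars <- stage("read", as.data.frame(
      data.table::fread(p$covar, sep = "\t", header = TRUE), stringsAsFactors = TRUE))
    for (nm in names(covars))
      if (is.character(covars[[nm]]) && nm != "sample_id")
        covars[[nm]] <- factor(covars[[nm]])
    annot <- list(
      islands = if (!is.null(p$islands)) read_bed(p$islands) else
        data.frame(chrom = character(), start = integer(), end = integer(),
                   name = character()),
      regions = if (!is.null(p$genes)) as.data.frame(
        data.table::fread(p$genes, sep = "\t", header = TRUE)) else
        data.frame(gene_id = character(), region = character(),
                   chrom = character(), start = integer(), end = integer()),
      expressed = list(wcb = if (!is.null(p$expressed)) readLines(p$expressed)
                       else character(0))
    )
    risk <- if (!is.null(p$risk_snps)) as.data.frame(
      data.table::fread(p$risk_snps, sep = "\t", header = TRUE)) else NULL
    inputs <- unlist(p)
  }
  manifest$input_md5 <- as.list(tools::md5sum(unname(inputs)))

  # ---- genotype QC --------------------------------------------------
  qc1 <- stage("geno_qc", filter_sample_callrate(geno))
  qc2 <- stage("geno_qc", filter_snps(qc1$geno))
  geno <- qc2$geno
  keep <- rownames(geno$dosage)
  meth <- subset_meth(meth, samples = match(keep, rownames(meth$values)))
  covars <- covars[match(keep, covars$sample_id), , drop = FALSE]
  write_tsv_df(qc2$report, file.path(config$out_dir, "geno_qc_report.tsv"))
  manifest$stages$geno_qc <- list(samples = nrow(geno$dosage),
                                  snps = ncol(geno$dosage))

  # ---- covariates + PCs --------------------------------------------
  if (config$n_pcs > 0) {
    pcs <- stage("geno_pcs", genotype_pcs(geno, config$n_pcs))
    covars <- cbind(covars, as.data.frame(pcs))
  }

  # ---- methylation prep --------------------------------------------
  if (meth$scale == "beta") {
    meth$values <- beta_to_m(meth$values)
    meth$scale <- "M"
  }
  if (!is.null(config$paths$exclude))
    meth <- stage("meth_prep",
                  exclusion_filter(meth, readLines(config$paths$exclude)))
  adj <- stage("meth_prep", residualize(meth, covars))
  manifest$stages$meth_prep <- list(sites = ncol(meth$values))

  # ---- annotation ---------------------------------------------------
  contexts <- stage("annotate", annotate_sites(meth$sites, annot))
  write_tsv_df(contexts, file.path(config$out_dir, "site_contexts.tsv"))

  # ---- regional heritability scan ----------------------------------
  rh <- stage("rh_scan",
              rh_scan(meth, geno, covars, half_window = config$window,
                      alpha = config$alpha,
                      covariate_mode = config$covariate_mode))
  write_tsv_df(rh$results, file.path(config$out_dir, "rh_results.tsv"))
  manifest$stages$rh_scan <- rh$summary

  # ---- GWAS ---------------------------------------------------------
  gwas <- stage("gwas", gwas_scan(adj$meth, geno,
                                  thresholds = config$thresholds,
                                  cis_window = config$window))
  write_tsv_df(gwas$summary, file.path(config$out_dir, "gwas_summary.tsv"))
  top <- stage("gwas", top_snp_vs_region(rh, gwas, geno, alpha = config$alpha))
  manifest$stages$gwas <- list(n_cis = unname(gwas$n_tests["cis"]),
                               n_trans = unname(gwas$n_tests["trans"]),
                               frac_region_ge_snp = top$frac_region_ge_snp)

  # ---- contextual statistics ---------------------------------------
  site_stats <- data.frame(
    site_id = rh$results$site_id,
    mean_m = colMeans(meth$values)[rh$results$site_id],
    resid_var = adj$resid_var[rh$results$site_id],
    h2 = rh$results$h2, p = rh$results$p, sigma_g2 = rh$results$sigma_g2,
    density = contexts$density[match(rh$results$site_id, contexts$site_id)],
    genic = contexts$genic[match(rh$results$site_id, contexts$site_id)]
  )
  ctx <- stage("summarize", context_summaries(site_stats, alpha = config$alpha))
  write_tsv_df(ctx$groups, file.path(config$out_dir, "context_groups.tsv"))
  part <- stage("summarize", h2_variance_partition(
    rh, adj$resid_var,
    setNames(paste(site_stats$density, site_stats$genic, sep = "."),
             site_stats$site_id),
    alpha = config$alpha))
  riskcmp <- if (!is.null(risk)) stage("summarize",
    risk_region_compare(rh, risk, half_window = config$window,
                        alpha = config$alpha)) else NULL

  manifest$stages$summarize <- list(
    n_groups = nrow(ctx$groups),
    snp_count_slope = if (!is.null(part)) part$snp_count$slope else NA
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(geno = geno, meth = meth, covars = covars, contexts = contexts,
                 rh = rh, gwas = gwas, top_snp = top, context_summary = ctx,
                 partition = part, risk = riskcmp, manifest = manifest))
}
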