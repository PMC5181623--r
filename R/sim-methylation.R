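#' Simulate covariates for a cohort
#'
#' Sex ~ Bernoulli(0.5), age ~ Uniform(30, 80) years, batch ~ categorical(4),
#' biopsy side ~ Bernoulli(0.5) (left/right colon), diagnosis ~
#' categorical(3).  Used both by the methylation generator (fixed effects
#' X beta) and directly when only a covariate table is needed.
#'
#' @param n_samples number of individuals.
#' @param sample_ids optional character ids (default `s0001`...).
#' @return data.frame with columns `sample_id, sex, age, batch, diagnosis,
#'   side`.
#' @export
sim_covariates <- function(n_samples, sample_ids = sprintf("s%04d", seq_len(n_samples))) {
  data.frame(
    sample_id = sample_ids,
    sex = factor(sample(c("F", "M"), n_samples, replace = TRUE), levels = c("F", "M")),
    age = round(runif(n_samples, 30, 80), 1),
    batch = factor(sample(sprintf("b%d", 1:4), n_samples, replace = TRUE),
                   levels = sprintf("b%d", 1:4)),
    diagnosis = factor(sample(c("polyp", "adenoma", "carcinoma"), n_samples, replace = TRUE),
                       levels = c("polyp", "adenoma", "carcinoma")),
    side = factor(sample(c("left", "right"), n_samples, replace = TRUE),
                  levels = c("left", "right")),
    stringsAsFactors = FALSE
  )
}

# fixed-effect contribution of the simulated covariates on the M scale
covariate_signal <- function(covars, effects) {
  eff <- function(name) if (name %in% names(effects)) effects[[name]] else 0
  eff("sex") * (covars$sex == "M") +
    eff("age") * (covars$age - 55) +
    eff("batch") * (as.integer(covars$batch) - 1) / 3 +
    eff("diagnosis") * (as.integer(covars$diagnosis) - 1) / 2 +
    eff("side") * (covars$side == "right")
}

# Genetic + noise phenotype component for one site.
# Draws `n_causal` causal SNPs from the window dosage matrix, gives them
# i.i.d. normal effects, and rescales the genetic component so that
# var(g) / (var(g) + var(e)) equals `h2` exactly in the realized sample.
# Returns list(y_rand, causal_ids, causal_effects).
sim_site_phenotype <- function(window_dosage, h2, n_causal, sigma_e2 = 1) {
  n <- nrow(window_dosage)
  eps <- rnorm(n, 0, sqrt(sigma_e2))
  if (h2 <= 0 || ncol(window_dosage) == 0L) {
    return(list(y_rand = eps, causal_ids = character(0),
                causal_effects = numeric(0)))
  }
  m <- ncol(window_dosage)
  if (m < n_causal) {
    warnf("window has %d SNPs < n_causal_per_site = %d; reducing", m, n_causal)
    n_causal <- m
  }
  idx <- sort(sample.int(m, n_causal))
  u <- rnorm(n_causal)
  G <- window_dosage[, idx, drop = FALSE]
  G[is.na(G)] <- 0
  g <- as.vector(G %*% u)
  vg <- var(g)
  ve <- var(eps)
  if (vg <= 0) {  # monomorphic draw; retry once with fresh effects
    return(list(y_rand = eps, causal_ids = character(0),
                causal_effects = numeric(0)))
  }
  s <- sqrt(h2 / (1 - h2) * ve / vg)
  list(y_rand = g * s + eps,
       causal_ids = colnames(window_dosage)[idx],
       causal_effects = u * s)
}

#' Simulate methylation phenotypes with known regional heritability
#'
#' For each CpG site, draws a target context from `config$context_mix` and
#' places the site inside the matching annotation stratum; draws a true
#' local heritability from `config$h2_dist`; samples causal SNPs from the
#' +/-1 Mb window around the site; and generates M-values under
#' `y = X beta + W u + e`, with the causal effects rescaled so the realized
#' genetic fraction of the random variance equals the drawn truth exactly.
#' Covariate effects are added through `X beta` (see [sim_covariates()]).
#'
#' @param geno a [genotype_data()] (typically from [sim_genotypes()]).
#' @param annot a `cpg_annotation` from [sim_annotation()].
#' @param config the [sim_config()] shared by all generator stages.
#' @return list with `meth` (a [methylation_data()] on the M scale),
#'   `covars` (data.frame), and `truth` (data.frame: `site_id, chrom, pos,
#'   density, genic, true_h2, causal_snps, causal_effects`; SNP lists are
#'   comma-separated).
#' @export
sim_methylation <- function(geno, annot, config) {
  stopifnot(inherits(geno, "genotype_data"), inherits(annot, "cpg_annotation"),
            inherits(config, "sim_config"))
  if (annot$chrom != config$chrom)
    stopf("annotation and config disagree on the chromosome")
  set.seed(config$seed + 3L)

  n <- nrow(geno$dosage)
  ns <- config$n_sites
  covars <- sim_covariates(n, rownames(geno$dosage))
  xb <- covariate_signal(covars, config$covariate_effects)

  cand <- context_candidates(annot)
  mix <- config$context_mix
  ctx <- sample(names(mix), ns, replace = TRUE, prob = mix)
  pos <- integer(ns)
  for (cx in unique(ctx)) {
    sel <- which(ctx == cx)
    ir <- cand[[cx]]
    if (is.null(ir) || length(ir) == 0L || sum(IRanges::width(ir)) == 0L)
      stopf("no candidate space for context '%s'; adjust the annotation config", cx)
    pos[sel] <- sample_positions_in(ir, length(sel))
  }
  ord <- order(pos)
  pos <- pos[ord]; ctx <- ctx[ord]

  h2 <- draw_h2(config$h2_dist, ns)
  snp_pos <- geno$snps$pos
  vals <- matrix(NA_real_, n, ns)
  causal_ids <- causal_eff <- character(ns)
  for (i in seq_len(ns)) {
    win <- which(snp_pos >= pos[i] - 1e6 & snp_pos <= pos[i] + 1e6)
    ph <- sim_site_phenotype(geno$dosage[, win, drop = FALSE], h2[i],
                             config$n_causal_per_site, config$sigma_e2)
    vals[, i] <- xb + ph$y_rand
    causal_ids[i] <- paste(ph$causal_ids, collapse = ",")
    causal_eff[i] <- paste(sprintf("%.6g", ph$causal_effects), collapse = ",")
  }
  site_id <- sprintf("cg%06d", seq_len(ns))
  density <- sub("\\..*$", "", ctx)
  genic <- sub("^[^.]*\\.", "", ctx)
  sites <- data.frame(chrom = config$chrom, pos = pos, id = site_id,
                      stringsAsFactors = FALSE)
  rownames(vals) <- rownames(geno$dosage)
  truth <- data.frame(site_id = site_id, chrom = config$chrom, pos = pos,
                      density = density, genic = genic, true_h2 = h2,
                      causal_snps = causal_ids, causal_effects = causal_eff,
                      stringsAsFactors = FALSE)
  list(meth = methylation_data(vals, sites, scale = "M"),
       covars = covars, truth = truth)
}

#' Simulate expression detection p-value matrices
#'
#' Produces, for each condition (WCB whole-tissue, LCM epithelium), a
#' samples-by-probes detection p-value matrix in which probes of expressed
#' genes are detected (p < `p_thresh`) in at least the strict >80% fraction
#' of samples and probes of non-expressed genes are not.
#'
#' @param annot a `cpg_annotation` (supplies the expressed-gene sets).
#' @param config a [sim_config()].
#' @param n_samples_condition named counts, default `c(wcb = 11, lcm = 9)`.
#' @param p_thresh detection threshold (default 0.01).
#' @param min_frac strict qualifying fraction (default 0.8).
#' @return list with matrices `wcb`, `lcm` (samples x probes) and
#'   `probe_gene` (data.frame `probe_id, gene_id`).
#' @export
sim_expression_detp <- function(annot, config,
                                n_samples_condition = c(wcb = 11, lcm = 9),
                                p_thresh = 0.01, min_frac = 0.8) {
  stopifnot(inherits(annot, "cpg_annotation"))
  set.seed(config$seed + 4L)
  genes <- annot$genes$gene_id
  probe_gene <- data.frame(probe_id = paste0(genes, "_p1"), gene_id = genes,
                           stringsAsFactors = FALSE)
  out <- list()
  for (cond in c("wcb", "lcm")) {
    ns <- n_samples_condition[[cond]]
    kmin <- min_detect_count(ns, min_frac)
    expressed <- annot$expressed[[cond]]
    mat <- matrix(NA_real_, ns, nrow(probe_gene),
                  dimnames = list(sprintf("%s_s%02d", cond, seq_len(ns)),
                                  probe_gene$probe_id))
    for (j in seq_along(genes)) {
      if (genes[j] %in% expressed) {
        k <- sample(kmin:ns, 1)
      } else {
        k <- sample(0:(kmin - 1L), 1)
      }
      det <- sample.int(ns, k)
      p <- runif(ns, p_thresh * 1.5, 1)
      p[det] <- runif(k, 0, p_thresh * 0.9)
      mat[, j] <- p
    }
    out[[cond]] <- mat
  }
  out$probe_gene <- probe_gene
  out
}
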