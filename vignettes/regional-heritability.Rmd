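---
title: "Regional heritability of CpG methylation: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional heritability of CpG methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgherit)
```

## The model

For one CpG site, let `y` be the vector of M-values across `n` unrelated
individuals (`M = log2(beta/(1-beta))`; the M scale decouples the
variance from the mean that the beta scale exhibits). With `X` a
fixed-effect design (intercept, sex, age, batch, diagnosis, biopsy side,
genotype principal components) and `W` the column-standardized dosages of
the `N` SNPs within ±1 Mb of the site,

    y = X beta + W u + e,   u ~ N(0, I sigma_u^2),   e ~ N(0, I sigma_e^2).

Integrating out `u` gives `y ~ N(X beta, A sigma_g^2 + I sigma_e^2)` with
`sigma_g^2 = N sigma_u^2` and the VanRaden relationship matrix
`A = W W' / N`, where column `j` of `W` is
`(g - 2 p_j) / sqrt(2 p_j (1 - p_j))` at sample allele frequency `p_j`
(missing dosages impute to `2 p_j`, i.e. 0 after centering; monomorphic
SNPs are dropped). The target parameter is the regional heritability

    h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2),

the proportion of (covariate-adjusted) methylation variance attributable
to SNPs in the window. The key assumptions are the usual GREML ones:
unrelated individuals, SNP effects exchangeable with a common variance,
Gaussian residuals, and causal variation tagged by the genotyped SNPs.

## REML by profile likelihood

`reml_fit()` maximizes the restricted likelihood over `h2` directly
rather than iterating on `(sigma_g^2, sigma_e^2)`:

1. eigendecompose `A = U D U'` once per site; eigenvalues below zero
   (numerical noise in rank-deficient windows) are clipped to zero and
   counted;
2. rotate `y* = U'y`, `X* = U'X`; the covariance becomes diagonal,
   `sigma_p^2 (h2 D + (1 - h2) I)`, so each likelihood evaluation is
   a weighted least-squares solve;
3. profile the total variance `sigma_p^2` out in closed form
   (REML denominator `n - p`), evaluate the restricted log-likelihood on
   a 512-point grid over `h2 in [0, 1 - 1e-6]`, and refine around the
   grid optimum by golden-section search to `|dh2| < 1e-6`.

At n in the low hundreds this costs a few milliseconds per site, cannot
diverge, and handles the boundary gracefully: if the profile is maximal
at `h2 = 0` (or entirely flat, as with `A = I`, where the two variance
components are unidentifiable) the fit reports `h2 = 0` with the null
log-likelihood. The null model is evaluated by the same code path with
`h2` pinned at 0, which guarantees nested comparability of the two
log-likelihoods. The test suite checks the optimum against a dense
10^4-point grid search over the textbook (Cholesky-based, untransformed)
restricted likelihood on randomized instances at n = 60.

## The boundary-mixture likelihood-ratio test

Under the null `sigma_g^2 = 0` the parameter lies on the boundary of the
parameter space, so the LRT statistic `T = 2 (ll_alt - ll_null)` is
asymptotically distributed as a 50:50 mixture of a point mass at zero
and a chi-square with 1 df:

```{r}
lrt_pvalue(3.841459 / 2, 0)   # T at the chi2_1 95th percentile -> 0.025
```

`p = 1` when `T = 0`, so p-values live in (0, 1] and never exceed 0.5
when `T > 0`. A site is declared heritable at nominal `p < 0.05` without
multiple-testing correction — the scan's purpose is an enrichment-style
census, and the null calibration is checked by simulation (below); a
Benjamini–Hochberg column is emitted alongside for users who want it.

## Covariates: fixed effects or pre-residualization

Two routes are exposed and give practically identical estimates:

* `covariate_mode = "fixed"` (default): covariates enter `X` inside the
  REML fit;
* `covariate_mode = "residualized"`: phenotypes are residualized on the
  covariate design by OLS first. The design is still carried in `X`
  during the REML fit — its GLS coefficients are then essentially zero,
  but the restricted likelihood keeps the same `n - p` degrees of
  freedom as the fixed-effect route, which removes the small upward bias
  in `sigma_p^2` that an intercept-only fit on residualized data incurs.

The test suite verifies mean `|h2|` differences below 0.02 between the
two routes on simulated data. The SNP-by-SNP association scan always
runs on residualized values (it mirrors a PLINK-style `--assoc` linear
regression on dosage).

## Window and coordinate conventions

* Point features (SNPs, the CpG cytosine) are 1-based; intervals
  (islands, gene regions) are 0-based half-open; conversion happens only
  at I/O boundaries (VCF/TSV vs BED).
* The regional window is inclusive at both endpoints: a SNP at exactly
  ±1,000,000 bp is in the window, and the same rule makes a SNP-site
  pair at exactly 1 Mb *cis* in the association scan, and a site exactly
  1 Mb from a risk SNP *within* the risk region.
* Island/shore/shelf geometry: shores are `(0, 2000]` bp from the island
  edge, shelves `(2000, 4000]`, sea beyond. "North" is the
  lower-coordinate side and "south" the higher-coordinate side,
  irrespective of gene strand (array manifests define these by genome
  orientation). The first base flanking an island has distance 1; signed
  distances are negative on the north side. Ties between two islands
  resolve to the upstream (north) relation.
* Island calling tiles the supplied sequence in fixed, consecutive
  500 bp frames starting at its first base (the published definition is
  frame-ambiguous; fixed framing makes output deterministic). A section
  qualifies iff `(C+G)/500 > 0.5` and `N_CpG * 500 / (N_C * N_G) > 0.60`;
  sections containing `N` never qualify; adjacent qualifying sections
  merge.
* TSS regions are strand-aware: TSS200 abuts the TSS on its 5' side and
  TSS1500 abuts TSS200. Genic classification applies successive filters
  (TSS of an expressed gene, TSS of any gene, gene body, intergenic), so
  every site receives exactly one label per axis.

## Genotype QC choices

* The Hardy–Weinberg test is the exact conditional test (probabilities
  of heterozygote counts given allele counts; two-sided by summing all
  configurations no more probable than the observed one). The exact test
  is the modern default and avoids small-count chi-square failure; the
  suite checks it against an independent enumeration oracle at 1e-12.
* The four SNP filters are successive — each applies to the survivors of
  the previous one — so removal counts attribute each SNP to exactly one
  filter. Allele frequencies use non-missing calls only and should be
  recomputed after sample filtering (the pipeline orders it that way).
* The X-chromosome inbreeding coefficient is `F = 1 - O(het)/E(het)`
  with `E(het) = sum 2 p (1 - p)` over the SNPs non-missing in the
  sample; recorded females with `F > 0.98` and males with `F < 0.2` are
  flagged. Mean imputation of missing dosages happens only inside
  standardization steps (PCs, GRM), never in stored data.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the study conditions the analysis is
designed for:

* 132 unrelated samples; one chromosome; SNP density 1.5e-4 per bp
  (300 SNPs per 2 Mb window); allele frequencies uniform on
  (0.05, 0.5); adjacent-haplotype copying probability `ld_rho = 0.2`.
* Context mix proportional to an island/sea by genic-context
  composition typical of autosomal 450K sites restricted to the two
  extreme density classes.
* Per-site truth: 5 causal SNPs drawn from the ±1 Mb window (a sparse
  cis architecture), effects i.i.d. normal then rescaled so the realized
  `var(Wu) / (var(Wu) + var(e))` equals the drawn `h2` exactly — at
  n = 132 this makes the recorded truth interpretable site by site
  rather than only in expectation. Residual variance 1 M-unit².
* Covariates: sex ~ Bernoulli(0.5); age ~ U(30, 80); batch ~
  categorical(4); side ~ Bernoulli(0.5); diagnosis ~ categorical(3);
  modest default effects (|beta| <= 0.5 M-units).
* Expression detection matrices honour the strict ">80% of samples"
  rule (11 samples -> 9; 9 samples -> 8), and the epithelial (LCM)
  expressed-gene set is a subset of the whole-biopsy (WCB) set apart
  from exactly ten epithelium-specific genes.

The LD model is a deliberate stand-in: first-order haplotype copying is
stationary, short-range and controlled by a single parameter, but it
does not reproduce real haplotype-block structure, allele-frequency–LD
coupling, or long-range LD. The generator also does not simulate raw
array intensities, probe-type (Infinium I/II) effects, or cell-type
mixtures. Passing tests therefore demonstrate statistical correctness of
the estimator and its calibration under the model's assumptions — not
robustness to array artefacts or cell-composition confounding in real
data.

## Calibration and recovery, at the sizes the tests use

Two simulation studies anchor the suite (both via `rh_sim_study()`,
which drives the generator and the estimator end to end):

* **Null calibration**: 1000 sites with `h2 = 0` (phenotype = covariate
  effects + Gaussian noise), n = 132, 300 window SNPs. The fraction with
  mixture-LRT `p < 0.05` must not exceed `0.05 + 3 sqrt(0.05*0.95/1000)
  ≈ 0.071`; observed fractions sit near or slightly below 0.05, as
  expected for the boundary mixture at finite n.
* **Recovery**: 200 sites at true `h2 = 0.3` (and 120 each at 0.1 and
  0.6 in the module tests), n = 132; the mean estimate must lie within
  ±0.05 of the truth. The estimator is near-unbiased here even though
  the generating architecture (5 causal SNPs) breaks the exchangeable
  SNP-effect assumption of the GREML model.

These sizes keep the whole default suite within a few minutes on one
CPU while leaving the Monte Carlo error well inside the asserted
tolerances.

## Degenerate inputs and tie-breaks

* Empty SNP window: the site is skipped, logged, and excluded from the
  scan denominator.
* `A = I` or flat profiles: reported at `h2 = 0` (see above), `p = 1`.
* Windows with fewer SNPs than the requested causal count: the causal
  count is reduced with a warning.
* Monomorphic SNPs: dropped before standardization; monomorphic
  genotypes in association tests give a no-test sentinel, and SNPs with
  minor allele count < 3 are excluded from the association totals.
* Minor-allele coding in the fixed-effect decomposition: by sample
  frequency, ties at 0.5 keeping the alternate allele.
* Top-SNP selection: smallest p, ties by larger r², then smaller
  genomic position.
* `alpha = 1`: every converged site counts as significant (p-values are
  capped at 1 by the point mass, so a strict `p < 1` comparison would
  exclude exact-boundary sites).

## Known limitations

* No genome-wide or per-chromosome polygenic fit: with ~10² unrelated
  samples the identity-by-state variance across the whole genome is too
  small for a stable estimate; the package is deliberately regional.
* Single variance component per site; no joint multi-window or
  multi-component models.
* Summaries of `h2` over significant sites only are subject to winner's
  curse (upward bias), which the contextual tables inherit by design;
  the descriptive 4-point correlations between proportion-heritable and
  mean genetic variance are flagged as descriptive.
* Expected association counts assume independent tests; LD makes them
  optimistic in cis, exactly as in the accounting convention they
  mirror.
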