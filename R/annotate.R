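#' Call CpG islands from genomic sequence
#'
#' Tiles the sequence into consecutive non-overlapping 500 bp sections
#' (framed from the start of the supplied sequence, i.e. from coordinate
#' `offset`).  A section qualifies iff its C+G density exceeds `gc_min`
#' and its observed/expected CpG ratio, `N_CpG * 500 / (N_C * N_G)`,
#' exceeds `oe_min`.  Maximal runs of adjacent qualifying sections are
#' merged into islands.  Sections containing `N` bases never qualify
#' (counted and reported via a message); a trailing partial section is
#' ignored.
#'
#' @param seq DNA sequence: a character string or a
#'   [Biostrings::DNAString] over `{A, C, G, T, N}`.
#' @param chrom chromosome name for the output intervals.
#' @param offset 0-based coordinate of the first base of `seq`.
#' @param section section length in bp (500).
#' @param gc_min minimum C+G density (0.5, strict).
#' @param oe_min minimum observed/expected CpG ratio (0.6, strict).
#' @return data.frame `chrom, start, end, name` (0-based half-open).
#' @export
call_islands <- function(seq, chrom = "chr1", offset = 0, section = 500L,
                         gc_min = 0.5, oe_min = 0.6) {
  s <- if (inherits(seq, "DNAString")) seq else Biostrings::DNAString(toupper(as.character(seq)))
  len <- length(s)
  nsec <- len %/% section
  if (nsec == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  starts <- (seq_len(nsec) - 1L) * section + 1L
  v <- Biostrings::Views(s, start = starts, width = section)
  freq <- Biostrings::letterFrequency(v, c("C", "G", "N"))
  ncpg <- Biostrings::vcountPattern("CG", v)
  nC <- freq[, "C"]; nG <- freq[, "G"]
  oe <- ifelse(nC > 0 & nG > 0, ncpg * section / (nC * nG), 0)
  qual <- (nC + nG) / section > gc_min & oe > oe_min & freq[, "N"] == 0
  n_with_n <- sum(freq[, "N"] > 0)
  if (n_with_n > 0)
    msgf("%d sections contain N and were treated as non-qualifying", n_with_n)
  if (!any(qual))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  runs <- which(r$values)
  data.frame(
    chrom = chrom,
    start = as.integer(offset + (begs[runs] - 1L) * section),
    end = as.integer(offset + ends[runs] * section),
    name = sprintf("island%03d", seq_along(runs)),
    stringsAsFactors = FALSE
  )
}

#' Classify CpG sites by distance from islands
#'
#' Each site receives one of six density classes: `island` (inside an
#' island), `shoreN`/`shoreS` (up to 2 kb upstream/downstream of an island,
#' i.e. at lower/higher genomic coordinate), `shelfN`/`shelfS` (2-4 kb),
#' or `sea` (beyond 4 kb or no island on the chromosome).  "North" is the
#' lower-coordinate side irrespective of gene strand.  Sites are assigned
#' to the nearest island; on an exact distance tie the upstream (north)
#' relation wins.  The signed distance is 0 inside islands, negative north
#' of the nearest island and positive south of it; the first base outside
#' an island has distance 1.
#'
#' @param pos 1-based site positions.
#' @param islands island intervals (data.frame `chrom,start,end`, 0-based
#'   half-open), assumed merged; they are re-merged defensively.
#' @param chrom optional chromosome per site (recycled); islands are
#'   matched per chromosome.
#' @return data.frame `density` (factor with the six levels) and
#'   `dist_signed` (bp; `NA` when the chromosome has no island).
#' @export
density_class <- function(pos, islands, chrom = NULL) {
  npos <- length(pos)
  if (is.null(chrom)) chrom <- rep(islands$chrom[1] %||% "chr1", npos)
  chrom <- rep_len(chrom, npos)
  density <- rep("sea", npos)
  dist <- rep(NA_real_, npos)
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    isl <- islands[islands$chrom == ch, , drop = FALSE]
    if (!nrow(isl)) next
    ir <- IRanges::reduce(iranges_of(isl))
    st <- IRanges::start(ir) - 1L  # back to 0-based
    en <- IRanges::end(ir)
    p0 <- pos[sel] - 1L
    for (k in seq_along(sel)) {
      x <- p0[k]
      i <- findInterval(x, st)  # islands with start <= x
      inside <- i >= 1L && x < en[i]
      if (inside) { density[sel[k]] <- "island"; dist[sel[k]] <- 0; next }
      dS <- if (i >= 1L) x - en[i] + 1L else Inf      # downstream of island i
      dN <- if (i < length(st)) st[i + 1L] - x else Inf  # upstream of island i+1
      if (dN <= dS) {  # tie prefers the upstream (north) relation
        dist[sel[k]] <- -dN
        density[sel[k]] <- if (dN <= 2000) "shoreN" else if (dN <= 4000) "shelfN" else "sea"
      } else {
        dist[sel[k]] <- dS
        density[sel[k]] <- if (dS <= 2000) "shoreS" else if (dS <= 4000) "shelfS" else "sea"
      }
      if (density[sel[k]] == "sea") dist[sel[k]] <- min(dN, dS) * sign(dist[sel[k]])
    }
  }
  data.frame(density = factor(density, levels = DENSITY_LEVELS),
             dist_signed = dist)
}

#' Minimal qualifying sample count under the strict >80% rule
#'
#' Smallest integer strictly greater than `min_frac * n`.
#'
#' @param n number of samples.
#' @param min_frac qualifying fraction (default 0.8, strict).
#' @return integer count.
#' @export
min_detect_count <- function(n, min_frac = 0.8) as.integer(floor(min_frac * n) + 1L)

#' Call expressed genes from a detection p-value matrix
#'
#' A probe qualifies iff it is detected above background (`p < p_thresh`)
#' in strictly more than `min_frac` of samples; a gene is expressed iff at
#' least one of its probes qualifies.  Probes without a gene mapping are
#' dropped with a logged count.
#'
#' @param detp samples x probes detection p-value matrix (column names are
#'   probe ids).
#' @param probe_gene data.frame `probe_id, gene_id`.
#' @param p_thresh detection threshold (default 0.01).
#' @param min_frac strict qualifying fraction (default 0.8).
#' @return character vector of expressed gene ids (sorted).
#' @export
expressed_gene_calls <- function(detp, probe_gene, p_thresh = 0.01, min_frac = 0.8) {
  stopifnot(min_frac > 0, min_frac < 1)
  detp <- as.matrix(detp)
  n <- nrow(detp)
  kmin <- min_detect_count(n, min_frac)
  counts <- colSums(detp < p_thresh)
  qual_probes <- colnames(detp)[counts >= kmin]
  mapped <- qual_probes %in% probe_gene$probe_id
  unmapped_all <- sum(!colnames(detp) %in% probe_gene$probe_id)
  if (unmapped_all > 0)
    msgf("%d probes had no gene mapping and were dropped", unmapped_all)
  sort(unique(probe_gene$gene_id[match(qual_probes[mapped], probe_gene$probe_id)]))
}

#' Classify CpG sites by genic context
#'
#' Mutually exclusive classes by successive filters, first match winning:
#' (1) within TSS200/TSS1500 of any expressed gene -> `tss_expressed`;
#' (2) within TSS200/TSS1500 of any gene -> `tss_not_expressed`;
#' (3) within 5'UTR/first exon/body/3'UTR of any gene -> `intragenic`;
#' (4) otherwise `intergenic`.  Gene sub-intervals are taken from the
#' annotation's region table (already strand-aware: upstream means 5' of
#' the TSS on the gene's strand).
#'
#' @param pos 1-based site positions.
#' @param regions gene-region table (`gene_id, region, chrom, start, end`,
#'   0-based half-open; regions named `tss200, tss1500, utr5, first_exon,
#'   body, utr3`).
#' @param expressed character vector of expressed gene ids.
#' @param chrom optional chromosome per site (recycled; single-chromosome
#'   region tables match any).
#' @return factor with levels `tss_expressed, tss_not_expressed,
#'   intragenic, intergenic`.
#' @export
genic_class <- function(pos, regions, expressed, chrom = NULL) {
  npos <- length(pos)
  sites <- IRanges::IRanges(start = pos, width = 1L)
  tier_ranges <- function(r) {
    if (!nrow(r)) return(IRanges::IRanges())
    IRanges::reduce(IRanges::IRanges(r$start + 1L, r$end))
  }
  tss <- regions[regions$region %in% c("tss200", "tss1500"), , drop = FALSE]
  gen <- regions[regions$region %in% c("utr5", "first_exon", "body", "utr3"), , drop = FALSE]
  in_tssE <- IRanges::overlapsAny(sites, tier_ranges(tss[tss$gene_id %in% expressed, ]))
  in_tssA <- IRanges::overlapsAny(sites, tier_ranges(tss))
  in_gen <- IRanges::overlapsAny(sites, tier_ranges(gen))
  out <- ifelse(in_tssE, "tss_expressed",
         ifelse(in_tssA, "tss_not_expressed",
         ifelse(in_gen, "intragenic", "intergenic")))
  factor(out, levels = GENIC_LEVELS)
}

#' Annotate CpG sites with both context labels
#'
#' Convenience wrapper combining [density_class()] and [genic_class()].
#'
#' @param sites data.frame `chrom, pos, id`.
#' @param annot a `cpg_annotation` (or a list with `islands`, `regions`,
#'   `expressed$wcb`).
#' @return data.frame `site_id, density, genic, dist_signed`.
#' @export
annotate_sites <- function(sites, annot) {
  dc <- density_class(sites$pos, annot$islands, chrom = sites$chrom)
  gc <- genic_class(sites$pos, annot$regions, annot$expressed$wcb,
                    chrom = sites$chrom)
  data.frame(site_id = sites$id, density = dc$density, genic = gc,
             dist_signed = dc$dist_signed, stringsAsFactors = FALSE)
}

#' Mean methylation as a function of distance from the island edge
#'
#' Bins site-level mean methylation by signed distance from the nearest
#' island edge (negative = north/upstream) in 100 bp bins over +/-4 kb and
#' returns the per-bin mean and standard error of the site means.  Bins
#' with a single site get `se = NA`; empty bins are emitted with `n = 0`
#' and missing mean.
#'
#' @param site_means per-site mean methylation (M scale).
#' @param dist_signed signed distances from [density_class()] (sites inside
#'   islands, distance 0, are excluded).
#' @param bin bin width in bp (100).
#' @param span half-range in bp (4000).
#' @return data.frame `bin_start, bin_mid, n, mean, se`.
#' @export
distance_profile <- function(site_means, dist_signed, bin = 100, span = 4000) {
  stopifnot(length(site_means) == length(dist_signed))
  breaks <- seq(-span, span, by = bin)
  keep <- !is.na(dist_signed) & dist_signed != 0 & abs(dist_signed) <= span
  d <- dist_signed[keep]; y <- site_means[keep]
  # distance d in (0, span]: bin index by ceiling; mirrored for negative
  idx <- ifelse(d > 0, ceiling(d / bin), -ceiling(-d / bin))
  levels_idx <- c(seq(-span / bin, -1), seq(1, span / bin))
  out <- data.frame(
    bin_start = ifelse(levels_idx < 0, levels_idx * bin, (levels_idx - 1) * bin),
    bin_mid = ifelse(levels_idx < 0, levels_idx * bin + bin / 2,
                     (levels_idx - 1) * bin + bin / 2)
  )
  out$n <- as.integer(table(factor(idx, levels = levels_idx)))
  agg_mean <- tapply(y, factor(idx, levels = levels_idx), mean)
  agg_sd <- tapply(y, factor(idx, levels = levels_idx), sd)
  out$mean <- as.numeric(agg_mean)
  out$se <- as.numeric(agg_sd) / sqrt(out$n)
  out$se[out$n < 2] <- NA_real_
  out$mean[out$n == 0] <- NA_real_
  out
}
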