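#' Simulate a genome annotation: CpG islands, gene models, expressed sets
#'
#' Generates a single-contig annotation with the structure the contextual
#' analysis needs: gene models with disjoint TSS1500/TSS200/5'UTR/first
#' exon/body/3'UTR sub-intervals (strand-aware), CpG islands placed over
#' some TSSs, inside some gene bodies and in intergenic space, and two
#' expressed-gene sets (whole-colon biopsy, WCB; laser-capture epithelium,
#' LCM) with the LCM set a subset of the WCB set apart from exactly ten
#' epithelium-specific genes.
#'
#' Genes are laid out on a regular grid of slots with randomised placement
#' inside each slot; slots are wide enough that the +/-4 kb shelf margin of
#' any island never reaches a neighbouring gene, so every one of the eight
#' island/sea by genic contexts has positive candidate space.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `cpg_annotation`: list with elements
#'   `islands` (data.frame `chrom,start,end,name`, 0-based half-open),
#'   `genes` (data.frame `gene_id,chrom,strand,tss,start,end`; `tss` is the
#'   1-based position of the transcription start base), `regions`
#'   (long data.frame `gene_id,region,chrom,start,end`), and `expressed`
#'   (list of character vectors `wcb`, `lcm`).
#' @export
sim_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  L <- config$chrom_length
  ng <- config$n_genes
  chrom <- config$chrom

  tss_mass <- sum(config$context_mix[grepl("tss|intragenic", names(config$context_mix))])
  if (ng == 0 && tss_mass > 0)
    stopf("degenerate config: genic contexts requested with zero genes")

  genes <- regions <- NULL
  if (ng > 0) {
    slot <- floor(L / ng)
    if (slot < 30000)
      stopf("chromosome too short for %d genes (need >= 30 kb per gene slot)", ng)
    # gene type controls island placement: island over the TSS, island in
    # the body, or no island at all
    gtype <- sample(c("tss_island", "body_island", "plain"), ng,
                    replace = TRUE, prob = c(0.5, 0.25, 0.25))
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    glen <- as.integer(round(runif(ng, 8000, 15000)))
    gene_id <- sprintf("gene%03d", seq_len(ng))
    tss <- integer(ng)
    reg_list <- vector("list", ng)
    isl_list <- list()
    margin <- 6000L  # keeps island shelves inside the slot
    for (i in seq_len(ng)) {
      lo <- (i - 1L) * slot + margin
      hi <- i * slot - margin - (glen[i] + 3000L)
      anchor <- as.integer(lo + floor(runif(1) * max(1, hi - lo)))
      # anchor = 0-based start of the 1500 bp upstream flank in + orientation
      t0 <- anchor + 1500L               # 0-based TSS coordinate (+ orientation)
      segs <- rbind(
        tss1500    = c(t0 - 1500L, t0 - 200L),
        tss200     = c(t0 - 200L,  t0),
        utr5       = c(t0,         t0 + 200L),
        first_exon = c(t0 + 200L,  t0 + 500L),
        body       = c(t0 + 500L,  t0 + glen[i] - 300L),
        utr3       = c(t0 + glen[i] - 300L, t0 + glen[i])
      )
      if (strand[i] == "-") {
        # reflect every interval about the TSS base so that "upstream"
        # means higher genomic coordinate
        refl <- cbind(2L * t0 + 1L - segs[, 2], 2L * t0 + 1L - segs[, 1])
        rownames(refl) <- rownames(segs)
        segs <- refl
      }
      tss[i] <- t0 + 1L  # 1-based
      reg_list[[i]] <- data.frame(
        gene_id = gene_id[i], region = rownames(segs), chrom = chrom,
        start = as.integer(segs[, 1]), end = as.integer(segs[, 2]),
        stringsAsFactors = FALSE
      )
      if (gtype[i] == "tss_island") {
        # island covering the whole TSS flank plus a little of the gene
        tssr <- segs[c("tss1500", "tss200"), , drop = FALSE]
        isl_list[[length(isl_list) + 1L]] <-
          c(min(tssr) - 100L, max(tssr) + 300L)
      } else if (gtype[i] == "body_island") {
        mid <- as.integer(round(mean(segs["body", ])))
        isl_list[[length(isl_list) + 1L]] <- c(mid - 400L, mid + 400L)
      }
    }
    regions <- do.call(rbind, reg_list)
    gstart <- vapply(reg_list, function(r) min(r$start), integer(1))
    gend <- vapply(reg_list, function(r) max(r$end), integer(1))
    genes <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                        tss = tss, start = gstart, end = gend,
                        stringsAsFactors = FALSE)
  } else {
    isl_list <- list()
    genes <- data.frame(gene_id = character(), chrom = character(),
                        strand = character(), tss = integer(),
                        start = integer(), end = integer())
    regions <- data.frame(gene_id = character(), region = character(),
                          chrom = character(), start = integer(),
                          end = integer())
  }

  # stand-alone intergenic islands, dropped into gaps between gene slots
  n_extra <- config$n_islands_intergenic
  if (n_extra > 0 && ng > 0) {
    slots <- sample.int(ng, min(n_extra, ng))
    for (s in slots) {
      # right-hand margin of slot s, clear of the gene and its shelves
      pos <- as.integer(s * floor(L / ng) - 5200L)
      isl_list[[length(isl_list) + 1L]] <- c(pos, pos + 600L)
    }
  } else if (n_extra > 0) {
    for (k in seq_len(n_extra)) {
      pos <- as.integer(round(runif(1, 5000, L - 6000)))
      isl_list[[length(isl_list) + 1L]] <- c(pos, pos + 600L)
    }
  }

  if (length(isl_list)) {
    isl <- do.call(rbind, isl_list)
    ir <- IRanges::reduce(IRanges::IRanges(isl[, 1] + 1L, isl[, 2]))
    islands <- iranges_to_df(ir, chrom,
                             name = sprintf("island%03d", seq_along(ir)))
  } else {
    islands <- data.frame(chrom = character(), start = integer(),
                          end = integer(), name = character())
  }

  # expressed-gene sets: LCM is a subset of WCB apart from exactly 10
  # epithelium-specific genes (when enough genes exist)
  expressed <- list(wcb = character(), lcm = character())
  if (ng > 0) {
    n_wcb <- max(1L, floor(ng / 2))
    wcb <- sort(sample(genes$gene_id, n_wcb))
    not_wcb <- setdiff(genes$gene_id, wcb)
    n_spec <- min(10L, length(not_wcb))
    lcm <- sort(c(sample(wcb, max(1L, floor(n_wcb / 2))),
                  sample(not_wcb, n_spec)))
    expressed <- list(wcb = wcb, lcm = lcm)
  }

  structure(list(chrom = chrom, chrom_length = L, islands = islands,
                 genes = genes, regions = regions, expressed = expressed),
            class = "cpg_annotation")
}

#' @export
print.cpg_annotation <- function(x, ...) {
  cat(sprintf("cpg_annotation: %s (%d bp), %d islands, %d genes (%d WCB / %d LCM expressed)\n",
              x$chrom, x$chrom_length, nrow(x$islands), nrow(x$genes),
              length(x$expressed$wcb), length(x$expressed$lcm)))
  invisible(x)
}

# Candidate 0-based half-open intervals for each of the eight contexts,
# with the same precedence semantics as genic_class() and the same
# island/shore/shelf geometry as density_class().
context_candidates <- function(annot) {
  L <- annot$chrom_length
  whole <- IRanges::IRanges(1L, L)
  isl <- if (nrow(annot$islands)) iranges_of(annot$islands) else IRanges::IRanges()
  isl <- IRanges::reduce(isl)
  near <- IRanges::reduce(IRanges::resize(isl, IRanges::width(isl) + 8000L, fix = "center"))
  sea <- IRanges::setdiff(whole, near)

  reg <- annot$regions
  pick <- function(gene_ids, regs) {
    r <- reg[reg$gene_id %in% gene_ids & reg$region %in% regs, , drop = FALSE]
    if (!nrow(r)) return(IRanges::IRanges())
    IRanges::reduce(IRanges::IRanges(r$start + 1L, r$end))
  }
  tss_regs <- c("tss200", "tss1500")
  gen_regs <- c("utr5", "first_exon", "body", "utr3")
  all_ids <- annot$genes$gene_id
  expr <- annot$expressed$wcb
  tssE <- pick(expr, tss_regs)
  tssA <- pick(all_ids, tss_regs)
  tssN <- IRanges::setdiff(tssA, tssE)
  intra <- IRanges::setdiff(pick(all_ids, gen_regs), tssA)
  inter <- IRanges::setdiff(IRanges::setdiff(whole, tssA), pick(all_ids, gen_regs))

  genic <- list(tss_expressed = tssE, tss_not_expressed = tssN,
                intragenic = intra, intergenic = inter)
  out <- list()
  for (d in c("island", "sea")) {
    dr <- if (d == "island") isl else sea
    for (g in names(genic))
      out[[paste(d, g, sep = ".")]] <- IRanges::intersect(dr, genic[[g]])
  }
  out
}
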