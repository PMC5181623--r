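test_that("island caller applies the GC and obs/exp thresholds", {
  cg <- strrep("CG", 250)        # GC = 1, obs/exp = 2 -> island
  at <- strrep("AT", 250)        # no C or G -> not
  gc_block <- paste0(strrep("G", 250), strrep("C", 250))  # GC = 1, zero CpG
  expect_equal(length(grep("CG", gc_block, fixed = TRUE)), 0)
  expect_equal(nrow(call_islands(cg)), 1)
  expect_equal(nrow(call_islands(at)), 0)
  expect_equal(nrow(call_islands(gc_block)), 0)
  # adjacent qualifying sections merge into one island
  isl <- call_islands(strrep("CG", 750))
  expect_equal(nrow(isl), 1)
  expect_equal(c(isl$start, isl$end), c(0, 1500))
  # output is invariant to splitting the sequence at a section boundary
  left <- call_islands(strrep("CG", 250))
  right <- call_islands(strrep("CG", 500), offset = 500)
  joint <- call_islands(strrep("CG", 750))
  expect_equal(IRanges::reduce(IRanges::IRanges(c(left$start, right$start) + 1L,
                                                c(left$end, right$end))),
               IRanges::IRanges(joint$start + 1L, joint$end))
  # sections containing N never qualify
  seqN <- paste0(strrep("CG", 250), paste0("N", strrep("CG", 249), "CG"))
  suppressMessages(isl2 <- call_islands(seqN))
  expect_equal(c(isl2$start, isl2$end), c(0, 500))
  # trailing partial section ignored
  expect_equal(nrow(call_islands(strrep("CG", 100))), 0)
})

test_that("density classes follow the island/shore/shelf/sea geometry", {
  isl <- data.frame(chrom = "chr1", start = 10000, end = 11000, name = "i1")
  cls <- function(pos) as.character(density_class(pos, isl)$density)
  expect_equal(cls(10500), "island")
  expect_equal(cls(9500), "shoreN")
  expect_equal(cls(11500), "shoreS")
  expect_equal(cls(7500), "shelfN")
  expect_equal(cls(13500), "shelfS")
  expect_equal(cls(16000), "sea")
  expect_equal(cls(5000), "sea")
  # boundary arithmetic: 1-based site pos p maps to 0-based p-1
  expect_equal(cls(10001), "island")   # first island base
  expect_equal(cls(10000), "shoreN")   # base immediately upstream
  expect_equal(cls(8001), "shoreN")    # exactly 2000 bp upstream
  expect_equal(cls(8000), "shelfN")    # 2001 bp upstream
  expect_equal(cls(13000), "shoreS")   # exactly 2000 bp downstream
  expect_equal(cls(15000), "shelfS")   # exactly 4000 bp downstream
  expect_equal(cls(15001), "sea")
  # signed distance: negative north, positive south, zero inside; the
  # first base flanking the island has distance 1
  d <- density_class(c(10500, 9500, 11500, 10000, 11001), isl)$dist_signed
  expect_equal(d, c(0, -501, 500, -1, 1))
  # no islands -> everything is sea
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character())
  expect_equal(cls2 <- as.character(density_class(c(1, 5e6), empty)$density),
               c("sea", "sea"))
  # exact tie between two islands prefers the upstream (north) relation
  isl2 <- data.frame(chrom = "chr1", start = c(0, 2998), end = c(1000, 4000),
                     name = c("a", "b"))
  tie <- density_class(2000, isl2)   # p0 = 1999: 1000 south of a, 999 north of b
  expect_equal(as.character(tie$density), "shoreN")
  # exact tie: p0 = 1998 is 999 south of a and 999 north of b -> north wins
  tie2 <- density_class(1999, data.frame(chrom = "chr1",
    start = c(0, 2997), end = c(1000, 4000), name = c("a", "b")))
  expect_equal(as.character(tie2$density), "shoreN")
  expect_lt(tie2$dist_signed, 0)
})

test_that("expressed-gene calls use the strict >80 percent rule", {
  expect_equal(min_detect_count(11), 9L)
  expect_equal(min_detect_count(9), 8L)
  expect_equal(min_detect_count(10), 9L)   # strictly greater than 8.0
  pg <- data.frame(probe_id = c("p1", "p2", "p3"),
                   gene_id = c("g1", "g1", "g2"))
  detp <- matrix(1, 10, 3, dimnames = list(NULL, c("p1", "p2", "p3")))
  detp[1:9, 1] <- 0.001   # qualifies (9 >= 9)
  detp[1:8, 3] <- 0.001   # does not (8 < 9)
  expect_equal(expressed_gene_calls(detp, pg), "g1")
  # one qualifying probe suffices for the gene
  detp[1:9, 3] <- 0.001
  expect_setequal(expressed_gene_calls(detp, pg), c("g1", "g2"))
  # unmapped probes dropped with a message
  colnames(detp)[2] <- "zzz"
  expect_message(expressed_gene_calls(detp, pg), "no gene mapping")
})

test_that("genic classes apply the successive-filter precedence", {
  regions <- data.frame(
    gene_id = c("gA", "gA", "gA", "gB", "gB"),
    region = c("tss1500", "tss200", "body", "tss200", "body"),
    chrom = "chr1",
    start = c(1000, 2300, 2500, 9000, 2400),
    end = c(2300, 2500, 5000, 9200, 2700)
  )
  cls <- function(pos, expressed = "gA")
    as.character(genic_class(pos, regions, expressed))
  # in TSS200 of expressed gA and the body of gB -> tss_expressed wins
  expect_equal(cls(2450), "tss_expressed")
  expect_equal(cls(2450, expressed = character(0)), "tss_not_expressed")
  expect_equal(cls(9100), "tss_not_expressed")  # tss of non-expressed gB
  expect_equal(cls(2600), "intragenic")         # body of both genes
  expect_equal(cls(3000), "intragenic")
  expect_equal(cls(8000), "intergenic")
  # invariant to gene-list order
  perm <- regions[c(4, 5, 1, 2, 3), ]
  expect_equal(as.character(genic_class(c(2450, 9100, 3000, 8000), perm, "gA")),
               c("tss_expressed", "tss_not_expressed", "intragenic", "intergenic"))
})

test_that("every site gets exactly one label on each axis", {
  cfg <- sim_config(seed = 17, n_sites = 150, n_samples = 10)
  annot <- sim_annotation(cfg)
  set.seed(99)
  pos <- sort(sample.int(cfg$chrom_length, 400))
  dc <- density_class(pos, annot$islands)
  gc <- genic_class(pos, annot$regions, annot$expressed$wcb)
  expect_false(any(is.na(dc$density)))
  expect_false(any(is.na(gc)))
  expect_true(all(dc$density %in% c("island", "shoreN", "shoreS",
                                    "shelfN", "shelfS", "sea")))
})

test_that("distance profile bins means and standard errors correctly", {
  # constant site means -> every occupied bin has mean c, se 0
  d <- c(-3950, -150, 150, 150, 3950)
  p <- distance_profile(rep(2.5, 5), d)
  occ <- p[p$n > 0, ]
  expect_true(all(occ$mean == 2.5))
  expect_equal(occ$se[occ$n > 1], 0)
  # single-site bins emit NA standard error
  expect_true(all(is.na(p$se[p$n == 1])))
  # 40 + 40 bins
  expect_equal(nrow(p), 80)
  # monotone gradient in distance -> monotone south-side bin means
  ds <- seq(50, 3950, by = 100)
  p2 <- distance_profile(ds / 1000, ds)
  south <- p2[p2$bin_start >= 0 & p2$n > 0, ]
  expect_true(all(diff(south$mean) > 0))
  # island sites (distance 0) are excluded
  p3 <- distance_profile(c(1, 9), c(0, 150))
  expect_equal(sum(p3$n), 1)
})
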