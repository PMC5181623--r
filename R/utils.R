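# Internal helpers shared across modules.

# Coordinate conventions used throughout the package:
#   * point features (SNPs, CpG sites): 1-based positions, as in VCF;
#   * intervals (islands, gene regions): 0-based half-open [start, end),
#     as in BED.  Conversions happen only at I/O boundaries.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
msgf  <- function(...) message(sprintf(...))

assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("`%s` must be a single value in [0, 1]", name)
  invisible(x)
}

# data.frame of intervals -> IRanges (per single chromosome slice)
iranges_of <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)  # IRanges is 1-based closed
}

iranges_to_df <- function(ir, chrom, name = NULL) {
  df <- data.frame(
    chrom = chrom,
    start = IRanges::start(ir) - 1L,
    end   = IRanges::end(ir),
    stringsAsFactors = FALSE
  )
  if (!is.null(name)) df$name <- name
  df
}

# uniform draw of integer positions (1-based) from a set of 0-based
# half-open intervals, proportional to width
sample_positions_in <- function(ir, n) {
  w <- IRanges::width(ir)
  if (length(ir) == 0L || sum(w) == 0L)
    stopf("cannot sample positions from an empty interval set")
  idx <- sample.int(length(ir), n, replace = TRUE, prob = w)
  offs <- floor(runif(n) * w[idx])
  IRanges::start(ir)[idx] + as.integer(offs)  # 1-based position inside interval
}

# density levels in fixed order
DENSITY_LEVELS <- c("island", "shoreN", "shoreS", "shelfN", "shelfS", "sea")
GENIC_LEVELS   <- c("tss_expressed", "tss_not_expressed", "intragenic", "intergenic")
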