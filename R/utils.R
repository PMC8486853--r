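# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# Intervals cross the package surface as BED-convention data frames
# (chrom, start, end; 0-based, half-open). GRanges is the internal engine.
as_granges <- function(df, chrom_lengths = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) > 0 && any(df$start < 0 | df$start >= df$end)) {
    stop("malformed interval: require 0 <= start < end")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  if (!is.null(chrom_lengths)) {
    bad <- setdiff(unique(as.character(df$chrom)), names(chrom_lengths))
    if (length(bad)) stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  }
  gr
}

as_bed_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# Nearest-edge gap between two BED interval sets (0 when overlapping/adjacent
# book-ended intervals count as gap 0 only if they truly share no base:
# [0,10) and [10,20) have gap 0 here, matching bedtools `closest -d` - 1 bp
# gap reported as 1). Returns the full distance matrix.
bed_gap <- function(a_start, a_end, b_start, b_end) {
  pmax(pmax(b_start - a_end, a_start - b_end), 0L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
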