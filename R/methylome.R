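# Single-cell CpG methylation: site/cell filtering, locus summaries, and
# pairwise dissimilarity over shared CpGs.
#
# Methylation calls travel as a long data.table with columns
# cell_id, chrom, pos, meth_count, total_count (one row per covered CpG per
# cell); `pos` is the 0-based position of the C on the plus strand.

.check_calls <- function(calls) {
  need <- c("cell_id", "chrom", "pos", "meth_count", "total_count")
  stopifnot(all(need %in% names(calls)))
  if (nrow(calls) && any(calls$meth_count > calls$total_count)) {
    stop("methylated count exceeds total count")
  }
  data.table::as.data.table(calls)
}

#' Filter CpG sites by read coverage
#'
#' Retains calls with coverage between `min_cov` and `max_cov` reads,
#' inclusive at both ends (the 3-100 read window drops unreliable
#' low-coverage sites and likely-artefactual pileups).
#'
#' @param calls long methylation call table (see module header).
#' @param min_cov,max_cov inclusive coverage bounds (defaults 3, 100).
#' @return the filtered call table.
#' @export
filter_cpg_sites <- function(calls, min_cov = 3L, max_cov = 100L) {
  calls <- .check_calls(calls)
  calls[calls$total_count >= min_cov & calls$total_count <= max_cov]
}

# map each call to a region index (NA when outside all regions);
# regions are BED half-open so pos in [start, end)
.site_region <- function(calls, regions) {
  gr_sites <- GenomicRanges::GRanges(calls$chrom,
                                     IRanges::IRanges(calls$pos + 1L,
                                                      calls$pos + 1L))
  gr_reg <- as_granges(regions)
  hit <- GenomicRanges::findOverlaps(gr_sites, gr_reg, select = "first")
  hit
}

#' Mean methylation per region per cell
#'
#' Mean of the per-site methylation rates (meth/total) over the covered
#' CpGs falling in each region, in percent. Regions with no covered site in
#' a cell are NA.
#'
#' @param calls filtered call table.
#' @param regions data.frame with chrom, start, end (and optionally a
#'   `name` column used as region id).
#' @return data.frame: cell_id, region, mean_meth (percent), n_sites.
#' @export
region_methylation <- function(calls, regions) {
  calls <- .check_calls(calls)
  region_id <- regions$name %||% sprintf("region_%d", seq_len(nrow(regions)))
  idx <- .site_region(calls, regions)
  dt <- calls[!is.na(idx)]
  dt$region <- region_id[idx[!is.na(idx)]]
  if (nrow(dt) == 0) {
    return(data.frame(cell_id = character(0), region = character(0),
                      mean_meth = numeric(0), n_sites = integer(0)))
  }
  dt$rate <- dt$meth_count / dt$total_count
  agg <- dt[, list(mean_meth = 100 * mean(rate), n_sites = .N),
            by = c("cell_id", "region")]
  as.data.frame(agg)
}

#' Filter cells by CpG site coverage within regions
#'
#' Keeps cells covering strictly more than `min_sites` distinct CpG sites
#' inside the region set (the >100-site rule for single-cell methylomes at
#' enhancer sets).
#'
#' @param calls filtered call table.
#' @param regions region data.frame.
#' @param min_sites site-count threshold (default 100, strict `>`).
#' @return character vector of retained cell ids.
#' @export
filter_cells_by_region_coverage <- function(calls, regions,
                                            min_sites = 100L) {
  calls <- .check_calls(calls)
  if (nrow(regions) == 0 || nrow(calls) == 0) return(character(0))
  idx <- .site_region(calls, regions)
  dt <- unique(calls[!is.na(idx), c("cell_id", "chrom", "pos"),
                     with = FALSE])
  cnt <- dt[, .N, by = "cell_id"]
  cnt$cell_id[cnt$N > min_sites]
}

#' Pairwise methylation dissimilarity between cells
#'
#' For each cell pair, over the CpG sites covered in both cells and lying
#' inside the region set, the dissimilarity is the mean absolute difference
#' of the per-site methylation rates, scaled to percent. For binary calls
#' this is exactly the fraction of discordant sites (0 = same status at
#' every shared site, 100 = different at every shared site). Pairs with no
#' shared site are NA and counted in the companion shared-site matrix as 0.
#'
#' @param calls filtered call table (cells already coverage-filtered).
#' @param regions non-empty region data.frame.
#' @param cells optional cell-id subset/ordering; defaults to all cells in
#'   `calls`.
#' @return list of class `meth_dissimilarity`: `d` (symmetric percent
#'   matrix, zero diagonal, NA for pairs without shared sites) and
#'   `n_shared` (shared-CpG count matrix).
#' @export
pairwise_dissimilarity <- function(calls, regions, cells = NULL) {
  calls <- .check_calls(calls)
  stopifnot(nrow(regions) > 0)
  cells <- cells %||% sort(unique(calls$cell_id))
  idx <- .site_region(calls, regions)
  dt <- calls[!is.na(idx) & calls$cell_id %in% cells]
  dt$rate <- dt$meth_count / dt$total_count
  dt$site <- paste(dt$chrom, dt$pos, sep = ":")
  n <- length(cells)
  d <- matrix(NA_real_, n, n, dimnames = list(cells, cells))
  ns <- matrix(0L, n, n, dimnames = list(cells, cells))
  diag(d) <- 0
  rates <- split(stats::setNames(dt$rate, dt$site), dt$cell_id)
  for (i in seq_len(n - 1)) {
    ri <- rates[[cells[i]]]
    for (j in (i + 1):n) {
      rj <- rates[[cells[j]]]
      shared <- intersect(names(ri), names(rj))
      ns[i, j] <- ns[j, i] <- length(shared)
      if (length(shared)) {
        val <- 100 * mean(abs(ri[shared] - rj[shared]))
        d[i, j] <- d[j, i] <- val
      }
    }
  }
  undef <- sum(is.na(d[upper.tri(d)]))
  if (undef > 0) {
    message(undef, " cell pair(s) share no covered CpG site; ",
            "their dissimilarity is undefined")
  }
  structure(list(d = d, n_shared = ns), class = "meth_dissimilarity")
}

#' Mean within-stage dissimilarity (methylation heterogeneity)
#'
#' Averages the defined pairwise dissimilarities over all within-stage cell
#' pairs; the per-stage mean is the stage's CpG-methylation heterogeneity.
#'
#' @param dissim a [pairwise_dissimilarity()] result.
#' @param stages named vector: cell id -> stage label.
#' @return data.frame: stage, mean_dissimilarity (percent), n_pairs.
#' @export
stage_heterogeneity <- function(dissim, stages) {
  stopifnot(inherits(dissim, "meth_dissimilarity"))
  cells <- rownames(dissim$d)
  stages <- stages[cells]
  out <- lapply(sort(unique(stages)), function(st) {
    idx <- which(stages == st)
    if (length(idx) < 2) stop("stage ", st, " has fewer than 2 cells")
    sub <- dissim$d[idx, idx]
    vals <- sub[upper.tri(sub)]
    data.frame(stage = st, mean_dissimilarity = mean(vals, na.rm = TRUE),
               n_pairs = sum(!is.na(vals)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summarize per-allele bisulfite calls at a locus
#'
#' For a reads x CpG matrix of calls (1 = methylated, 0 = unmethylated, NA =
#' not sequenced), returns the column-wise percent methylated and row-wise
#' mean methylation over non-missing entries, as produced by locus-specific
#' or ChIP-bisulfite sequencing.
#'
#' @param allele_matrix numeric/logical matrix with NA for missing.
#' @return list: `per_cpg_percent` (NA where a column is all-missing, with
#'   a message), `per_read_mean` (fraction scale).
#' @export
allele_methylation_summary <- function(allele_matrix) {
  m <- as.matrix(allele_matrix)
  if (nrow(m) < 1) stop("need at least one read (row)")
  col_n <- colSums(!is.na(m))
  if (any(col_n == 0)) {
    message(sum(col_n == 0), " CpG column(s) with no sequenced read; ",
            "percent methylation undefined")
  }
  per_cpg <- ifelse(col_n > 0, 100 * colSums(m == 1, na.rm = TRUE) / col_n,
                    NA_real_)
  per_read <- rowMeans(m, na.rm = TRUE)
  list(per_cpg_percent = per_cpg, per_read_mean = per_read)
}
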