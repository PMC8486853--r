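# Enhancer-catalog construction: replicate-peak merging, promoter/blacklist
# subtraction, capture Hi-C anchor linking, and proximal gene assignment.
# All intervals are BED-convention data frames (0-based half-open);
# GenomicRanges/IRanges does the interval arithmetic internally.
#
# Distance convention: the gap in bp between nearest edges, 0 when the
# features overlap. A TSS is a 1-bp feature at its position.

#' Merge peak lists, fusing peaks within a gap
#'
#' Takes the union of all input peak lists and fuses any two intervals that
#' overlap or are separated by at most `gap_bp` bases ("within 1 kb" merging
#' of replicate peaks; the boundary is inclusive, matching `bedtools merge
#' -d` semantics). The result is sorted and disjoint with all pairwise gaps
#' strictly greater than `gap_bp`.
#'
#' @param peak_lists a list of interval data.frames (chrom, start, end), or
#'   a single data.frame.
#' @param gap_bp maximal gap that still merges (default 1000).
#' @return sorted disjoint interval data.frame.
#' @export
merge_peaks <- function(peak_lists, gap_bp = 1000L) {
  stopifnot(gap_bp >= 0)
  if (is.data.frame(peak_lists)) peak_lists <- list(peak_lists)
  grs <- lapply(peak_lists, as_granges)
  all_gr <- do.call(c, grs)
  merged <- GenomicRanges::reduce(all_gr, min.gapwidth = gap_bp + 1L)
  df <- as_bed_df(GenomicRanges::sort(merged))
  rownames(df) <- NULL
  df
}

#' Subtract promoter and blacklist regions from peaks
#'
#' Removes every base covered by a mask region (typically promoters defined
#' as TSS +/- 2 kb, plus an assay blacklist) from the peak set; peak pieces
#' reduced to zero length are dropped.
#'
#' @param intervals peak data.frame (chrom, start, end).
#' @param masks one mask data.frame or a list of them (all are unioned).
#' @return data.frame of the surviving peak pieces, sorted.
#' @export
subtract_regions <- function(intervals, masks) {
  if (is.data.frame(masks)) masks <- list(masks)
  masks <- masks[vapply(masks, function(m) !is.null(m) && nrow(m) > 0,
                        logical(1))]
  gr <- as_granges(intervals)
  if (length(masks) == 0) return(as_bed_df(GenomicRanges::sort(gr)))
  mask_gr <- GenomicRanges::reduce(do.call(c, lapply(masks, as_granges)))
  kept <- GenomicRanges::setdiff(gr, mask_gr)
  as_bed_df(GenomicRanges::sort(kept))
}

#' Promoter mask from gene models
#'
#' TSS +/- `flank` bp for every gene, clipped at chromosome bounds.
#'
#' @param genes data.frame with chrom, tss (and optionally strand; the TSS
#'   column is already the strand-aware 5' end).
#' @param flank promoter half-width (default 2000).
#' @param chrom_lengths named lengths for clipping (optional).
#' @return interval data.frame.
#' @export
promoter_mask <- function(genes, flank = 2000L, chrom_lengths = NULL) {
  start <- pmax(genes$tss - flank, 0L)
  end <- genes$tss + flank
  if (!is.null(chrom_lengths)) {
    end <- pmin(end, unname(chrom_lengths[genes$chrom]))
  }
  data.frame(chrom = genes$chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

# gap between interval sets a and b (data frames), full matrix in bp;
# 0 when overlapping.
.gap_matrix <- function(a, b) {
  out <- matrix(Inf, nrow(a), nrow(b))
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    out[ia, ib] <- outer(seq_along(ia), seq_along(ib), function(i, j) {
      bed_gap(a$start[ia[i]], a$end[ia[i]], b$start[ib[j]], b$end[ib[j]])
    })
  }
  out
}

# distance matrix between intervals (rows) and TSS point positions
# (columns): 0 when the point is covered, otherwise the coordinate
# difference to the nearest covered base ("edge X bp from the TSS").
.tss_gap_matrix <- function(a, tss) {
  out <- matrix(Inf, nrow(a), nrow(tss))
  for (ch in intersect(unique(a$chrom), unique(tss$chrom))) {
    ia <- which(a$chrom == ch)
    ib <- which(tss$chrom == ch)
    out[ia, ib] <- outer(seq_along(ia), seq_along(ib), function(i, j) {
      s <- a$start[ia[i]]
      e <- a$end[ia[i]]
      t <- tss$tss[ib[j]]
      ifelse(t >= s & t < e, 0, ifelse(t < s, s - t, t - e + 1))
    })
  }
  out
}

#' Link distal peaks to genes through interaction anchor pairs
#'
#' A (peak, gene) link is emitted when one anchor of an interaction pair
#' lies within `peak_dist` of the peak and the other anchor lies within
#' `tss_dist` of the gene's TSS; both anchor orderings are tested, so the
#' operation is symmetric in anchor order. One record per linked peak
#' aggregates all its genes.
#'
#' @param peaks distal peak data.frame (chrom, start, end); row order gives
#'   the peak ids `peak_<i>` unless a `peak_id` column is present.
#' @param interactions BEDPE-style data.frame (chrom1..end2).
#' @param genes gene table (gene_id, chrom, tss).
#' @param gene_set character vector of gene ids eligible for linking
#'   (e.g. the PGCLC gene set); defaults to all genes.
#' @param peak_dist maximal anchor-to-peak gap in bp (default 1000,
#'   inclusive).
#' @param tss_dist maximal anchor-to-TSS gap in bp (default 3000,
#'   inclusive).
#' @return data.frame of enhancer records: peak_id, chrom, start, end,
#'   linked_genes (comma-joined), n_genes, source = "interaction".
#' @export
link_enhancers <- function(peaks, interactions, genes, gene_set = NULL,
                           peak_dist = 1000L, tss_dist = 3000L) {
  gene_set <- gene_set %||% genes$gene_id
  missing_g <- setdiff(gene_set, genes$gene_id)
  if (length(missing_g)) {
    stop("gene_set gene(s) missing from gene table: ",
         paste(utils::head(missing_g, 5), collapse = ", "))
  }
  gs <- genes[genes$gene_id %in% gene_set, , drop = FALSE]
  peak_id <- peaks$peak_id %||% sprintf("peak_%d", seq_len(nrow(peaks)))

  a1 <- data.frame(chrom = interactions$chrom1, start = interactions$start1,
                   end = interactions$end1)
  a2 <- data.frame(chrom = interactions$chrom2, start = interactions$start2,
                   end = interactions$end2)
  links <- list()
  for (orient in 1:2) {
    pa <- if (orient == 1) a1 else a2 # anchor tested against peaks
    ga <- if (orient == 1) a2 else a1 # anchor tested against TSSs
    gp <- .gap_matrix(pa, peaks) # pairs x peaks
    gt <- .tss_gap_matrix(ga, gs) # pairs x genes
    hit_p <- which(gp <= peak_dist, arr.ind = TRUE)
    hit_t <- which(gt <= tss_dist, arr.ind = TRUE)
    if (nrow(hit_p) == 0 || nrow(hit_t) == 0) next
    pk_by_pair <- split(hit_p[, 2], hit_p[, 1])
    gn_by_pair <- split(hit_t[, 2], hit_t[, 1])
    common <- intersect(names(pk_by_pair), names(gn_by_pair))
    for (pr in common) {
      links[[length(links) + 1L]] <- expand.grid(
        peak = pk_by_pair[[pr]], gene = gn_by_pair[[pr]])
    }
  }
  if (length(links) == 0) {
    return(data.frame(peak_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      linked_genes = character(0), n_genes = integer(0),
                      source = character(0), stringsAsFactors = FALSE))
  }
  lk <- unique(do.call(rbind, links))
  by_peak <- split(gs$gene_id[lk$gene], lk$peak)
  idx <- as.integer(names(by_peak))
  data.frame(
    peak_id = peak_id[idx],
    chrom = peaks$chrom[idx], start = peaks$start[idx], end = peaks$end[idx],
    linked_genes = vapply(by_peak, function(g)
      paste(sort(unique(g)), collapse = ","), character(1)),
    n_genes = vapply(by_peak, function(g) length(unique(g)), integer(1)),
    source = "interaction", row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign peaks to proximal gene-set genes
#'
#' Keeps peaks within `max_dist` of the nearest gene-set TSS while
#' discarding promoter-proximal peaks (distance to the nearest TSS of any
#' gene must exceed `min_tss_dist`). Each surviving peak is assigned the
#' nearest gene-set gene (ties broken by gene id).
#'
#' @inheritParams link_enhancers
#' @param max_dist maximal distance to a gene-set TSS (default 500 kb).
#' @param min_tss_dist minimal distance to any TSS (default 3.5 kb, strict).
#' @return data.frame: peak_id, chrom, start, end, linked_genes, n_genes,
#'   source = "proximal", tss_distance.
#' @export
assign_proximal <- function(peaks, genes, gene_set = NULL,
                            max_dist = 500000L, min_tss_dist = 3500L) {
  gene_set <- gene_set %||% genes$gene_id
  gs <- genes[genes$gene_id %in% gene_set, , drop = FALSE]
  peak_id <- peaks$peak_id %||% sprintf("peak_%d", seq_len(nrow(peaks)))

  gap_any <- .tss_gap_matrix(peaks, genes)
  gap_set <- .tss_gap_matrix(peaks, gs)
  d_any <- apply(gap_any, 1, min)
  d_set <- apply(gap_set, 1, min)
  keep <- which(d_set <= max_dist & d_any > min_tss_dist)
  if (length(keep) == 0) {
    return(data.frame(peak_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      linked_genes = character(0), n_genes = integer(0),
                      source = character(0), tss_distance = numeric(0),
                      stringsAsFactors = FALSE))
  }
  nearest <- vapply(keep, function(i) {
    d <- gap_set[i, ]
    cand <- gs$gene_id[d == min(d)]
    sort(cand)[1] # deterministic tie-break: lexicographic gene id
  }, character(1))
  data.frame(peak_id = peak_id[keep], chrom = peaks$chrom[keep],
             start = peaks$start[keep], end = peaks$end[keep],
             linked_genes = nearest, n_genes = 1L, source = "proximal",
             tss_distance = d_set[keep], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Enhancers-per-gene ratio of a catalog
#'
#' Number of enhancer records divided by the number of distinct linked
#' genes, rounded to one decimal (e.g. 415 enhancers over 216 genes gives
#' 1.9 enhancers/gene).
#'
#' @param records enhancer record data.frame with a `linked_genes` column
#'   (comma-joined gene ids).
#' @return the ratio, one decimal.
#' @export
enhancers_per_gene <- function(records) {
  stopifnot(nrow(records) > 0)
  genes <- unique(unlist(strsplit(records$linked_genes, ",", fixed = TRUE)))
  genes <- genes[!is.na(genes) & nzchar(genes)]
  if (length(genes) == 0) stop("no linked genes in the record set")
  round(nrow(records) / length(genes), 1)
}
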