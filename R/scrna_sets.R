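#' Per-cell normalization of UMI counts
#'
#' Counts are scaled to `scale_factor` per cell (counts-per-10k by default)
#' and optionally log-transformed (`log1p`), the standard single-cell
#' normalization this package uses for differential testing, gating and
#' variable-gene selection.
#'
#' @param counts genes x cells integer matrix, or a `umi_counts` object.
#' @param scale_factor per-cell target sum (default 1e4).
#' @param log apply `log1p` (default TRUE).
#' @return numeric matrix of the same shape.
#' @export
normalize_umi <- function(counts, scale_factor = 1e4, log = TRUE) {
  if (inherits(counts, "umi_counts")) counts <- counts$counts
  totals <- colSums(counts)
  if (any(totals == 0)) stop("cell(s) with zero total counts")
  norm <- sweep(counts, 2, totals / scale_factor, "/")
  if (log) log1p(norm) else norm
}

#' Define a marker gene set by differential expression with fraction filters
#'
#' Genes are tested target vs background on per-cell normalized expression
#' with a pluggable two-sample test (default: two-sided Wilcoxon rank-sum),
#' p-values are Benjamini-Hochberg adjusted, and members must be
#' upregulated (positive log2 fold change) with, strictly, adjusted
#' p < `padj`, fraction expressing in the target `pct.1` > `pct1_min`, and
#' fraction expressing in the background `pct.2` < `pct2_max`.
#'
#' @param umi a `umi_counts` object or genes x cells count matrix.
#' @param target_cells,background_cells disjoint non-empty cell-id sets.
#' @param padj adjusted p-value ceiling (default 0.005, strict `<`).
#' @param pct1_min minimal expressing fraction in the target (default 0.2,
#'   strict `>`).
#' @param pct2_max maximal expressing fraction in the background (default
#'   0.4, strict `<`).
#' @param test function(values_target, values_background) returning a
#'   p-value; defaults to a two-sided `wilcox.test`.
#' @return list of class `gene_set_result`: `table` (gene, p, padj, pct1,
#'   pct2, log2fc, member) and `members` (character vector).
#' @export
define_gene_set <- function(umi, target_cells, background_cells,
                            padj = 0.005, pct1_min = 0.2, pct2_max = 0.4,
                            test = NULL) {
  counts <- if (inherits(umi, "umi_counts")) umi$counts else umi
  if (length(target_cells) == 0 || length(background_cells) == 0) {
    stop("target and background cell sets must be non-empty")
  }
  if (length(intersect(target_cells, background_cells))) {
    stop("target and background cell sets must be disjoint")
  }
  missing_c <- setdiff(c(target_cells, background_cells), colnames(counts))
  if (length(missing_c)) {
    stop("cell id(s) not in matrix: ", paste(utils::head(missing_c, 5),
                                             collapse = ", "))
  }
  test <- test %||% function(a, b) {
    suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  }
  norm <- normalize_umi(counts[, c(target_cells, background_cells),
                                drop = FALSE], log = FALSE)
  tg <- norm[, target_cells, drop = FALSE]
  bg <- norm[, background_cells, drop = FALSE]
  raw_t <- counts[, target_cells, drop = FALSE]
  raw_b <- counts[, background_cells, drop = FALSE]
  pct1 <- rowMeans(raw_t > 0)
  pct2 <- rowMeans(raw_b > 0)
  log2fc <- log2((rowMeans(tg) + 1) / (rowMeans(bg) + 1))
  p <- vapply(seq_len(nrow(norm)), function(g) {
    a <- tg[g, ]
    b <- bg[g, ]
    if (all(a == a[1]) && all(b == a[1])) return(1) # constant gene
    test(a, b)
  }, numeric(1))
  pa <- p.adjust(p, method = "BH")
  member <- pa < padj & pct1 > pct1_min & pct2 < pct2_max & log2fc > 0
  tab <- data.frame(gene = rownames(counts), p = p, padj = pa,
                    pct1 = pct1, pct2 = pct2, log2fc = log2fc,
                    member = member, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, members = tab$gene[tab$member]),
            class = "gene_set_result")
}

#' Transcriptional noise of a stage
#'
#' Within a stage, the `n_variable_genes` most variable genes (ranked by
#' dispersion, variance/mean of per-cell normalized counts) are selected;
#' all cell pairs are compared by Spearman correlation over those genes and
#' the correlations are mapped to distances `d = sqrt((1 - rho) / 2)`, so
#' d = 0 for identically ranked cells, 1 for exactly reversed ranks, and
#' sqrt(0.5) at rho = 0. Cells with constant expression over the selected
#' genes have undefined rho; their pairs are excluded with a warning.
#'
#' @param umi a `umi_counts` object (with `cell_meta$stage`) or a count
#'   matrix (then all columns are taken as the stage).
#' @param stage stage label to analyse.
#' @param n_variable_genes number of genes to rank over (default 500;
#'   capped at the number of genes with nonzero variance).
#' @return list of class `noise_result`: `stage`, `d` (symmetric matrix,
#'   zero diagonal, NA for excluded pairs), `pairs` (long data.frame),
#'   `variable_genes`.
#' @export
transcriptional_noise <- function(umi, stage = NULL,
                                  n_variable_genes = 500L) {
  if (inherits(umi, "umi_counts")) {
    cells <- if (is.null(stage)) umi$cell_meta$cell_id else
      umi$cell_meta$cell_id[umi$cell_meta$stage == stage]
    counts <- umi$counts[, cells, drop = FALSE]
  } else {
    counts <- umi
  }
  if (ncol(counts) < 3) stop("need at least 3 cells in the stage")
  norm <- normalize_umi(counts, log = FALSE)
  mu <- rowMeans(norm)
  v <- apply(norm, 1, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  usable <- which(v > 0)
  if (length(usable) < 2) stop("too few genes with nonzero variance")
  n_take <- min(n_variable_genes, length(usable))
  sel <- usable[order(disp[usable], decreasing = TRUE)[seq_len(n_take)]]
  sub <- norm[sel, , drop = FALSE]
  constant <- apply(sub, 2, function(z) var(z) == 0)
  if (any(constant)) {
    warning(sum(constant), " cell(s) constant over the selected genes; ",
            "their pairs are excluded")
  }
  rho <- suppressWarnings(cor(sub, method = "spearman"))
  rho[constant, ] <- NA
  rho[, constant] <- NA
  d <- sqrt((1 - rho) / 2)
  diag(d) <- 0
  ut <- which(upper.tri(d), arr.ind = TRUE)
  pairs <- data.frame(cell1 = colnames(d)[ut[, 1]],
                      cell2 = colnames(d)[ut[, 2]],
                      d = d[ut], stringsAsFactors = FALSE)
  structure(list(stage = stage %||% NA_character_, d = d,
                 pairs = pairs[!is.na(pairs$d), , drop = FALSE],
                 variable_genes = rownames(norm)[sel]),
            class = "noise_result")
}

#' Gate PGCLC-like cells by marker expression
#'
#' Returns the cells satisfying `(Dppa3 > dppa3) OR (Prdm1 > prdm1)`, AND
#' `Klf4 < klf4` — i.e. germ-cell markers on, the naive-pluripotency marker
#' off. A cell at or above the Klf4 threshold is never gated in, whatever
#' its Dppa3/Prdm1 expression. Thresholds apply to normalized (log1p CP10K)
#' expression by default.
#'
#' @param umi a `umi_counts` object or count matrix containing the three
#'   gating genes.
#' @param dppa3,prdm1,klf4 thresholds (defaults 0.1, 1, 1).
#' @param normalized gate on normalized expression (default TRUE) or raw
#'   counts.
#' @return character vector of gated-in cell ids.
#' @export
gate_pgclc_cells <- function(umi, dppa3 = 0.1, prdm1 = 1, klf4 = 1,
                             normalized = TRUE) {
  counts <- if (inherits(umi, "umi_counts")) umi$counts else umi
  need <- c("Dppa3", "Prdm1", "Klf4")
  missing_g <- setdiff(need, rownames(counts))
  if (length(missing_g)) {
    stop("gating gene(s) missing from matrix: ",
         paste(missing_g, collapse = ", "))
  }
  expr <- if (normalized) normalize_umi(counts) else counts
  gated <- (expr["Dppa3", ] > dppa3 | expr["Prdm1", ] > prdm1) &
    expr["Klf4", ] < klf4
  colnames(counts)[gated]
}

#' Cluster cells on a low-dimensional embedding
#'
#' k-means on the embedding coordinates (t-SNE/UMAP computation itself is an
#' upstream input), with 10 restarts and the best within-cluster sum of
#' squares; deterministic for a fixed seed.
#'
#' @param embedding cells x >=2 numeric matrix (rownames = cell ids).
#' @param k number of clusters (>= 2, <= number of cells).
#' @param seed RNG seed.
#' @return integer vector of cluster labels named by cell id.
#' @export
cluster_cells <- function(embedding, k, seed = 1L) {
  embedding <- as.matrix(embedding)
  if (k < 2 || k > nrow(embedding)) {
    stop("k must be between 2 and the number of cells")
  }
  fit <- with_seed(seed, kmeans(embedding, centers = k, nstart = 10L))
  stats::setNames(fit$cluster, rownames(embedding))
}

#' Annotate clusters by marker-set enrichment
#'
#' For each cluster, its upregulated genes (cluster vs all other cells,
#' same test as [define_gene_set()] with fraction filters disabled and
#' `up_padj` significance) are tested for enrichment of each candidate
#' tissue's markers with a one-sided hypergeometric test. Marker sets are
#' expected to be pre-filtered to strong markers (the source screen keeps
#' log2 fold change > 2.5). The cluster is labelled with the most
#' significantly enriched tissue; clusters with no BH-adjusted enrichment
#' below `floor` are labelled `"undefined"`.
#'
#' @param umi a `umi_counts` object or count matrix.
#' @param clusters named vector of cluster labels per cell id.
#' @param marker_sets named list: tissue -> character vector of marker
#'   genes.
#' @param up_padj adjusted-p ceiling for calling a gene cluster-upregulated
#'   (default 0.05).
#' @param floor BH-adjusted enrichment significance floor (default 0.05).
#' @return data.frame: cluster, label, p (enrichment p of the chosen
#'   tissue), padj, n_up.
#' @export
annotate_clusters <- function(umi, clusters, marker_sets,
                              up_padj = 0.05, floor = 0.05) {
  counts <- if (inherits(umi, "umi_counts")) umi$counts else umi
  if (length(marker_sets) == 0 || any(!vapply(marker_sets, length,
                                              integer(1)))) {
    stop("marker_sets must be a non-empty list of non-empty gene vectors")
  }
  marker_sets <- marker_sets[order(names(marker_sets))] # order-invariant
  universe <- rownames(counts)
  out <- lapply(sort(unique(clusters)), function(cl) {
    in_cells <- names(clusters)[clusters == cl]
    out_cells <- setdiff(colnames(counts), in_cells)
    gs <- define_gene_set(counts, in_cells, out_cells, padj = up_padj,
                          pct1_min = 0, pct2_max = 1)
    up <- gs$members
    enr <- vapply(marker_sets, function(mk) {
      mk <- intersect(mk, universe)
      q <- length(intersect(up, mk))
      phyper(q - 1, length(mk), length(universe) - length(mk),
             length(up), lower.tail = FALSE)
    }, numeric(1))
    enr_adj <- p.adjust(enr, method = "BH")
    best <- which.min(enr)
    data.frame(cluster = cl,
               label = if (enr_adj[best] < floor)
                 names(marker_sets)[best] else "undefined",
               p = unname(enr[best]), padj = unname(enr_adj[best]),
               n_up = length(up), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mean expression of a gene set per cell
#'
#' Arithmetic mean of the set's per-gene values within each cell, on
#' whatever expression scale the supplied matrix carries (raw UMI or
#' normalized).
#'
#' @param expr genes x cells numeric matrix (or `umi_counts`, using raw
#'   counts).
#' @param gene_set character vector of gene ids.
#' @return named numeric vector, one mean per cell.
#' @export
mean_gene_set_expression <- function(expr, gene_set) {
  if (inherits(expr, "umi_counts")) expr <- expr$counts
  present <- intersect(gene_set, rownames(expr))
  if (length(present) == 0) stop("gene set does not intersect the matrix")
  colMeans(expr[present, , drop = FALSE])
}

#' Cluster composition percentages
#'
#' Percentage of cells carrying each cluster label, to one decimal (e.g.
#' 162 of 1416 cells in a PGCLC cluster is 11.4%).
#'
#' @param labels vector of per-cell cluster labels.
#' @return named numeric vector of percentages summing to ~100.
#' @export
cluster_composition <- function(labels) {
  stopifnot(length(labels) > 0)
  tab <- table(labels)
  stats::setNames(round(100 * as.numeric(tab) / length(labels), 1),
                  names(tab))
}
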