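# Gene-set definition, transcriptional noise, gating, clustering,
# annotation.

test_that("gene-set membership applies all three filters strictly", {
  # fixed-p injected test isolates the threshold logic from the test stat
  set.seed(1)
  counts <- matrix(rpois(20 * 5, 2), nrow = 5,
                   dimnames = list(paste0("gg", 1:5), paste0("c", 1:20)))
  tgt <- paste0("c", 1:10)
  bgd <- paste0("c", 11:20)
  # clear member: expressed in all targets, nowhere in background
  counts["gg1", ] <- c(rep(5L, 10), rep(0L, 10))
  res <- define_gene_set(counts, tgt, bgd,
                         test = function(a, b) 1e-6)
  expect_true("gg1" %in% res$members)
  tab <- res$table[res$table$gene == "gg1", ]
  expect_equal(tab$pct1, 1)
  expect_equal(tab$pct2, 0)
  # padj exactly at the threshold is excluded (strict <)
  res2 <- define_gene_set(counts, tgt, bgd, test = function(a, b) 0.005)
  expect_false("gg1" %in% res2$members)
  # pct1 exactly at the bound is excluded (strict >)
  counts["gg2", ] <- c(rep(1L, 2), rep(0L, 8), rep(0L, 10))
  res3 <- define_gene_set(counts, tgt, bgd, test = function(a, b) 1e-6)
  expect_equal(res3$table$pct1[res3$table$gene == "gg2"], 0.2)
  expect_false("gg2" %in% res3$members)
  # pct2 exactly at the bound is excluded (strict <)
  counts["gg3", ] <- c(rep(6L, 10), rep(1L, 4), rep(0L, 6))
  res4 <- define_gene_set(counts, tgt, bgd, test = function(a, b) 1e-6)
  expect_equal(res4$table$pct2[res4$table$gene == "gg3"], 0.4)
  expect_false("gg3" %in% res4$members)
  # downregulated genes are never members
  counts["gg4", ] <- c(rep(0L, 9), 1L, rep(8L, 4), rep(0L, 6))
  res5 <- define_gene_set(counts, tgt, bgd, test = function(a, b) 1e-6)
  expect_false("gg4" %in% res5$members)
  # input validation
  expect_error(define_gene_set(counts, character(0), bgd), "non-empty")
  expect_error(define_gene_set(counts, tgt, tgt), "disjoint")
})

test_that("planted markers are recovered and agree with a permutation oracle", {
  cfg <- sim_config(seed = 3, umi = list(
    stages = c(ESC = 3L, EpiLC = 3L, EpiSC = 3L),
    eb_clusters = c(PGCLC = 100L, ExEctoderm = 100L)))
  u <- gen_umi_matrix(cfg)
  pg <- u$cell_meta$cell_id[u$cell_meta$cluster == "PGCLC"]
  bg <- u$cell_meta$cell_id[u$cell_meta$cluster == "ExEctoderm"]
  res <- define_gene_set(u, pg, bg)
  planted <- u$marker_sets$PGCLC
  expect_setequal(intersect(res$members, planted), planted) # all 20 found
  nulls <- grep("^null", rownames(u$counts), value = TRUE)
  expect_length(intersect(res$members, nulls), 0) # no false positives
  # independent check: permutation test on normalized means agrees on a
  # sample of planted and null genes
  norm <- normalize_umi(u$counts[, c(pg, bg)], log = FALSE)
  for (gene in planted[1:5]) {
    expect_lt(perm_test_mean_diff(norm[gene, pg], norm[gene, bg], B = 400),
              0.01)
  }
  set.seed(11)
  for (gene in sample(nulls, 10)) {
    expect_gt(perm_test_mean_diff(norm[gene, pg], norm[gene, bg], B = 400),
              0.005)
  }
})

test_that("gene-set output is invariant to cell and gene permutation", {
  cfg <- sim_config(seed = 8, umi = list(
    stages = c(ESC = 3L, EpiLC = 3L, EpiSC = 3L),
    n_genes = 120L,
    eb_clusters = c(PGCLC = 30L, ExEctoderm = 30L)))
  u <- gen_umi_matrix(cfg)
  pg <- u$cell_meta$cell_id[u$cell_meta$cluster == "PGCLC"]
  bg <- u$cell_meta$cell_id[u$cell_meta$cluster == "ExEctoderm"]
  ref <- define_gene_set(u$counts, pg, bg)
  set.seed(2)
  shuf <- u$counts[sample(nrow(u$counts)), sample(ncol(u$counts))]
  per <- define_gene_set(shuf, sample(pg), sample(bg))
  expect_setequal(ref$members, per$members)
})

test_that("noise distances hit the closed forms at rho = 1, -1, 0", {
  counts <- cbind(
    same = c(1L, 2L, 3L, 4L),
    scaled = c(2L, 4L, 6L, 8L), # same ranks -> rho 1 -> d 0
    ortho = c(2L, 4L, 1L, 3L), # rho 0 vs `same` -> d sqrt(0.5)
    rev = c(4L, 3L, 2L, 1L) # reversed ranks -> rho -1 -> d 1
  )
  rownames(counts) <- paste0("gn", 1:4)
  nr <- transcriptional_noise(counts, n_variable_genes = 4L)
  expect_equal(nr$d["same", "scaled"], 0)
  expect_equal(nr$d["same", "ortho"], sqrt(0.5))
  expect_equal(nr$d["same", "rev"], 1)
  expect_true(isSymmetric(nr$d))
  expect_true(all(diag(nr$d) == 0))
  expect_true(all(nr$pairs$d >= 0 & nr$pairs$d <= 1))
})

test_that("constant cells are excluded from noise pairs with a warning", {
  counts <- cbind(a = c(1L, 2L, 3L), b = c(2L, 1L, 3L), flat = c(2L, 2L, 2L))
  rownames(counts) <- paste0("gn", 1:3)
  expect_warning(nr <- transcriptional_noise(counts, n_variable_genes = 3L),
                 "constant")
  expect_true(is.na(nr$d["a", "flat"]))
  expect_false(any(nr$pairs$cell1 == "flat" | nr$pairs$cell2 == "flat"))
})

test_that("the lowest-dispersion stage has the lowest noise", {
  cfg <- sim_config(seed = 9)
  u <- gen_umi_matrix(cfg)
  med <- vapply(c("ESC", "EpiLC", "EpiSC"), function(st) {
    median(transcriptional_noise(u, st)$pairs$d)
  }, numeric(1))
  expect_equal(names(which.min(med)), "EpiLC") # planted lowest dispersion
  # one-sided check that the separation is real, not a tie
  esc <- transcriptional_noise(u, "ESC")$pairs$d
  epi <- transcriptional_noise(u, "EpiLC")$pairs$d
  wt <- wilcox.test(epi, esc, alternative = "less")
  expect_lt(wt$p.value, 0.01)
})

test_that("PGCLC gating applies thresholds with Klf4 precedence", {
  expr <- rbind(
    Dppa3 = c(0.5, 0.05, 0, 0, 5),
    Prdm1 = c(0, 2, 0, 2, 5),
    Klf4 = c(0, 2, 0, 0.5, 1)
  )
  colnames(expr) <- paste0("c", 1:5)
  gated <- gate_pgclc_cells(expr, normalized = FALSE)
  expect_setequal(gated, c("c1", "c4"))
  # c2 fails despite Prdm1 > 1 (Klf4 too high); c5 at Klf4 == 1 is out
  expect_false("c2" %in% gated)
  expect_false("c5" %in% gated)
  # precedence property on random matrices: Klf4 >= 1 is never gated in
  set.seed(3)
  rnd <- matrix(runif(3 * 200, 0, 3), nrow = 3,
                dimnames = list(c("Dppa3", "Prdm1", "Klf4"),
                                paste0("r", 1:200)))
  g <- gate_pgclc_cells(rnd, normalized = FALSE)
  expect_true(all(rnd["Klf4", g] < 1))
  expect_error(gate_pgclc_cells(rnd[1:2, , drop = FALSE],
                                normalized = FALSE), "Klf4")
})

test_that("k-means clustering is deterministic and recovers planted blobs", {
  cfg <- sim_config(seed = 11)
  u <- gen_umi_matrix(cfg)
  eb <- u$cell_meta[u$cell_meta$stage == "d4EB", ]
  emb <- as.matrix(eb[, c("emb1", "emb2")])
  rownames(emb) <- eb$cell_id
  cl1 <- cluster_cells(emb, k = 4, seed = 11)
  cl2 <- cluster_cells(emb, k = 4, seed = 11)
  expect_identical(cl1, cl2)
  ari <- mclust::adjustedRandIndex(cl1, eb$cluster)
  expect_gte(ari, 0.99)
  expect_error(cluster_cells(emb, k = nrow(emb) + 1), "between 2")
  # two well-separated blobs, k = 2
  blob <- rbind(matrix(rnorm(40, 0, 0.1), ncol = 2),
                matrix(rnorm(40, 5, 0.1), ncol = 2))
  rownames(blob) <- paste0("b", 1:40)
  lab <- cluster_cells(blob, k = 2, seed = 1)
  expect_equal(length(unique(lab[1:20])), 1)
  expect_equal(length(unique(lab[21:40])), 1)
  expect_false(lab[1] == lab[21])
})

test_that("clusters are annotated by their most enriched marker set", {
  cfg <- sim_config(seed = 12, umi = list(
    stages = c(ESC = 40L, EpiLC = 3L, EpiSC = 3L)))
  u <- gen_umi_matrix(cfg)
  eb <- u$cell_meta[u$cell_meta$stage == "d4EB", ]
  clusters <- stats::setNames(eb$cluster, eb$cell_id)
  # restrict the matrix to EB + ESC cells; the ESC group expresses no
  # marker set and must come out undefined
  esc <- u$cell_meta$cell_id[u$cell_meta$stage == "ESC"]
  clusters <- c(clusters, stats::setNames(rep("escgroup", length(esc)), esc))
  counts <- u$counts[, names(clusters)]
  ann <- annotate_clusters(counts, clusters, u$marker_sets)
  for (cl in names(u$marker_sets)) {
    expect_equal(ann$label[ann$cluster == cl], cl)
  }
  expect_equal(ann$label[ann$cluster == "escgroup"], "undefined")
  # invariance to marker-set order
  ann2 <- annotate_clusters(counts, clusters, rev(u$marker_sets))
  expect_equal(ann$label[order(ann$cluster)],
               ann2$label[order(ann2$cluster)])
  expect_error(annotate_clusters(counts, clusters, list()), "non-empty")
})

test_that("mean gene-set expression is a per-cell arithmetic mean", {
  expr <- rbind(g1 = c(2, 0), g2 = c(4, 0), g3 = c(10, 10))
  colnames(expr) <- c("cellA", "cellB")
  expect_equal(unname(mean_gene_set_expression(expr, c("g1", "g2"))),
               c(3, 0))
  expect_equal(unname(mean_gene_set_expression(expr, "g3")), c(10, 10))
  expect_error(mean_gene_set_expression(expr, "absent"), "intersect")
})

test_that("cluster composition percentages are reported to one decimal", {
  labels <- c(rep("PGCLC", 162), rep("other", 1416 - 162))
  expect_equal(unname(cluster_composition(labels)["PGCLC"]), 11.4)
})
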