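# CpG filtering, region summaries and pairwise methylation dissimilarity.

mk_calls <- function(cell, pos, meth, total, chrom = "chr1") {
  data.table::data.table(cell_id = cell, chrom = chrom, pos = pos,
                         meth_count = meth, total_count = total)
}

test_that("site coverage filter is inclusive at 3 and 100 reads", {
  calls <- mk_calls("c1", pos = 1:4, meth = c(1L, 1L, 50L, 50L),
                    total = c(2L, 3L, 100L, 101L))
  kept <- filter_cpg_sites(calls)
  expect_equal(kept$total_count, c(3L, 100L))
  expect_equal(nrow(filter_cpg_sites(calls[0, ])), 0)
  # brute-force agreement on a random methylome
  set.seed(21)
  rnd <- mk_calls("c1", pos = 1:500, meth = 0L,
                  total = sample.int(150, 500, replace = TRUE))
  rnd$meth_count <- as.integer(floor(rnd$total_count / 2))
  expect_equal(filter_cpg_sites(rnd)$pos,
               rnd$pos[rnd$total_count >= 3 & rnd$total_count <= 100])
  bad <- mk_calls("c1", pos = 1L, meth = 5L, total = 3L)
  expect_error(filter_cpg_sites(bad), "exceeds")
})

test_that("region methylation averages per-site rates in percent", {
  calls <- mk_calls("c1", pos = c(10L, 20L, 500L), meth = c(0L, 5L, 5L),
                    total = c(5L, 5L, 5L))
  regions <- data.frame(chrom = "chr1", start = 0L, end = 100L,
                        name = "enh1")
  rm1 <- region_methylation(calls, regions)
  expect_equal(rm1$mean_meth, 50) # rates {0, 1} -> 50%
  expect_equal(rm1$n_sites, 2L)
  # no covered sites: region absent from the summary
  empty <- region_methylation(calls, data.frame(chrom = "chr1",
                                                start = 1000L, end = 2000L,
                                                name = "none"))
  expect_equal(nrow(empty), 0)
  # fully methylated methylome
  full <- mk_calls("c1", pos = c(10L, 20L), meth = c(4L, 9L),
                   total = c(4L, 9L))
  expect_equal(region_methylation(full, regions)$mean_meth, 100)
})

test_that("cell filtering by region site count is strict at the threshold", {
  regions <- data.frame(chrom = "chr1", start = 0L, end = 10000L)
  at <- mk_calls("at", pos = 1:100, meth = 1L, total = 3L)
  above <- mk_calls("above", pos = 1:101, meth = 1L, total = 3L)
  calls <- rbind(at, above)
  expect_equal(filter_cells_by_region_coverage(calls, regions), "above")
  expect_equal(filter_cells_by_region_coverage(calls, regions[0, ]),
               character(0))
  # counts match a brute-force tally under a random region subset
  set.seed(22)
  rnd <- data.table::rbindlist(lapply(paste0("r", 1:5), function(cc)
    mk_calls(cc, pos = sort(sample.int(5000, 300)), meth = 1L, total = 5L)))
  reg2 <- data.frame(chrom = "chr1", start = c(0L, 2500L),
                     end = c(1000L, 4000L))
  got <- filter_cells_by_region_coverage(rnd, reg2, min_sites = 80)
  brute <- vapply(paste0("r", 1:5), function(cc) {
    p <- rnd$pos[rnd$cell_id == cc]
    sum((p >= 0 & p < 1000) | (p >= 2500 & p < 4000))
  }, numeric(1))
  expect_setequal(got, names(brute)[brute > 80])
})

test_that("pairwise dissimilarity matches the stated arithmetic", {
  regions <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  a <- mk_calls("a", pos = c(1L, 2L, 3L), meth = c(0L, 5L, 5L),
                total = c(5L, 5L, 5L))
  b <- mk_calls("b", pos = c(1L, 2L, 3L), meth = c(5L, 5L, 0L),
                total = c(5L, 5L, 5L))
  d <- pairwise_dissimilarity(rbind(a, b), regions)
  expect_equal(d$d["a", "b"], (1 + 0 + 1) / 3 * 100, tolerance = 1e-9)
  expect_equal(d$n_shared["a", "b"], 3L)
  # identical methylomes -> 0; fully discordant binary -> 100
  a2 <- data.table::copy(a)
  a2$cell_id <- "a2"
  expect_equal(pairwise_dissimilarity(rbind(a, a2), regions)$d["a", "a2"], 0)
  inv <- data.table::copy(a)
  inv$cell_id <- "inv"
  inv$meth_count <- 5L - inv$meth_count
  expect_equal(pairwise_dissimilarity(rbind(a, inv), regions)$d["a", "inv"],
               100)
  # disjoint coverage -> undefined entry, flagged not zero
  c2 <- mk_calls("c2", pos = c(900L, 901L), meth = 1L, total = 4L)
  expect_message(dd <- pairwise_dissimilarity(rbind(a, c2), regions),
                 "share no covered")
  expect_true(is.na(dd$d["a", "c2"]))
  expect_equal(dd$n_shared["a", "c2"], 0L)
})

test_that("on binary methylomes the rate formula equals discordant-site fraction", {
  set.seed(23)
  regions <- data.frame(chrom = "chr1", start = 0L, end = 100000L)
  for (i in 1:10) {
    pos <- sort(sample.int(99000, 60))
    cover_a <- runif(60) < 0.8
    cover_b <- runif(60) < 0.8
    a <- mk_calls("a", pos = pos[cover_a],
                  meth = as.integer(runif(sum(cover_a)) < 0.5) * 4L,
                  total = 4L)
    b <- mk_calls("b", pos = pos[cover_b],
                  meth = as.integer(runif(sum(cover_b)) < 0.5) * 4L,
                  total = 4L)
    d <- suppressMessages(pairwise_dissimilarity(rbind(a, b), regions))
    shared <- intersect(a$pos, b$pos)
    if (length(shared) == 0) {
      expect_true(is.na(d$d["a", "b"]))
    } else {
      sa <- a$meth_count[match(shared, a$pos)] > 0
      sb <- b$meth_count[match(shared, b$pos)] > 0
      expect_equal(d$d["a", "b"], 100 * mean(sa != sb), tolerance = 1e-9)
    }
    # symmetry / diagonal / bounds
    expect_true(isSymmetric(d$d))
    expect_true(all(diag(d$d) == 0))
    expect_true(all(d$d >= 0 & d$d <= 100, na.rm = TRUE))
  }
})

test_that("restricting regions never increases shared-site counts", {
  cfg <- sim_config(seed = 14, meth = list(stage_cells = c(A = 6L),
                                           stage_var = c(A = 0.04)))
  g <- gen_genome(cfg)
  m <- gen_methylomes(g, cfg)
  enh <- g$enhancers[g$enhancers$class != "decoy", c("chrom", "start", "end")]
  full <- suppressMessages(pairwise_dissimilarity(m$calls, enh))
  part <- suppressMessages(
    pairwise_dissimilarity(m$calls, enh[seq_len(20), ]))
  expect_true(all(part$n_shared <= full$n_shared))
})

test_that("planted heterogeneity levels are recovered in order", {
  cfg <- sim_config(seed = 15)
  g <- gen_genome(cfg)
  m <- gen_methylomes(g, cfg)
  enh <- g$enhancers[g$enhancers$class != "decoy", c("chrom", "start", "end")]
  calls <- filter_cpg_sites(m$calls)
  keep <- filter_cells_by_region_coverage(calls, enh)
  expect_gt(length(keep), 30) # dense toy coverage passes the >100-site rule
  dis <- suppressMessages(
    pairwise_dissimilarity(calls[calls$cell_id %in% keep], enh,
                           cells = keep))
  het <- stage_heterogeneity(dis, stats::setNames(m$cell_meta$stage,
                                                  m$cell_meta$cell_id))
  obs <- stats::setNames(het$mean_dissimilarity, het$stage)
  planted <- cfg$meth$stage_var[names(obs)]
  # strictly ordered across the three planted variance levels
  expect_equal(cor(obs, planted, method = "spearman"), 1)
  expect_true(all(diff(sort(obs)) > 0))
  expect_error(stage_heterogeneity(dis, stats::setNames(
    c("solo", rep("rest", length(keep) - 1)), keep)), "fewer than 2")
})

test_that("allele matrices are summarized over non-missing calls", {
  m <- matrix(1, nrow = 10, ncol = 3)
  s <- allele_methylation_summary(m)
  expect_equal(unname(s$per_cpg_percent), rep(100, 3))
  # half methylated, half missing -> 100% over sequenced reads
  m2 <- matrix(c(1, 1, NA, NA), ncol = 1)
  expect_equal(unname(allele_methylation_summary(m2)$per_cpg_percent), 100)
  m3 <- matrix(NA_real_, nrow = 4, ncol = 1)
  expect_message(s3 <- allele_methylation_summary(cbind(m2, m3)),
                 "no sequenced")
  expect_true(is.na(s3$per_cpg_percent[2]))
  # random matrix vs brute-force tallies
  set.seed(24)
  r <- matrix(sample(c(0, 1, NA), 60, replace = TRUE), nrow = 6)
  sr <- allele_methylation_summary(r)
  for (j in seq_len(ncol(r))) {
    col <- r[, j][!is.na(r[, j])]
    if (length(col)) {
      expect_equal(unname(sr$per_cpg_percent[j]), 100 * mean(col == 1))
    }
  }
  for (i in seq_len(nrow(r))) {
    row <- r[i, ][!is.na(r[i, ])]
    expect_equal(unname(sr$per_read_mean[i]), mean(row))
  }
})
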