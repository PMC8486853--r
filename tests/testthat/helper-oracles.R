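# Independent brute-force oracles used by the tests. These deliberately
# avoid the package's interval engine (GenomicRanges) and its statistics:
# everything here is plain-vector arithmetic or exhaustive enumeration.

# transitive-closure interval merge: any two intervals with edge gap
# <= gap_bp (or overlapping) end up in one block
brute_merge <- function(df, gap_bp) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    cur_s <- sub$start[1]
    cur_e <- sub$end[1]
    if (nrow(sub) > 1) {
      for (i in 2:nrow(sub)) {
        if (sub$start[i] - cur_e <= gap_bp) {
          cur_e <- max(cur_e, sub$end[i])
        } else {
          out[[length(out) + 1]] <- data.frame(chrom = ch, start = cur_s,
                                               end = cur_e)
          cur_s <- sub$start[i]
          cur_e <- sub$end[i]
        }
      }
    }
    out[[length(out) + 1]] <- data.frame(chrom = ch, start = cur_s,
                                         end = cur_e)
  }
  do.call(rbind, out)
}

# set of covered bases (chrom:pos strings) of an interval data frame
base_set <- function(df) {
  if (nrow(df) == 0) return(character(0))
  unlist(lapply(seq_len(nrow(df)), function(i) {
    if (df$end[i] <= df$start[i]) return(character(0))
    paste(df$chrom[i], df$start[i]:(df$end[i] - 1), sep = ":")
  }))
}

# per-base window mean over [start, end) on a fixed-bin track
brute_window_mean <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  pos <- start:(end - 1)
  mean(v[pos %/% track$bin_size + 1])
}

# edge-gap between two half-open intervals, 0 if overlapping
oracle_gap <- function(s1, e1, s2, e2) max(s2 - e1, s1 - e2, 0)

# distance between an interval and a TSS point (0 if covered)
oracle_tss_dist <- function(s, e, t) {
  if (t >= s && t < e) 0 else if (t < s) s - t else t - e + 1
}

# all-pairs scan: which (peak, gene) pairs does an interaction set support?
brute_link <- function(peaks, interactions, genes, peak_dist, tss_dist) {
  hits <- list()
  for (p in seq_len(nrow(interactions))) {
    anchors <- list(
      list(chrom = interactions$chrom1[p], s = interactions$start1[p],
           e = interactions$end1[p]),
      list(chrom = interactions$chrom2[p], s = interactions$start2[p],
           e = interactions$end2[p]))
    for (ord in 1:2) {
      pa <- anchors[[ord]]
      ga <- anchors[[3 - ord]]
      for (k in seq_len(nrow(peaks))) {
        if (peaks$chrom[k] != pa$chrom) next
        if (oracle_gap(pa$s, pa$e, peaks$start[k], peaks$end[k]) > peak_dist) next
        for (gi in seq_len(nrow(genes))) {
          if (genes$chrom[gi] != ga$chrom) next
          if (oracle_tss_dist(ga$s, ga$e, genes$tss[gi]) > tss_dist) next
          hits[[length(hits) + 1]] <- data.frame(
            peak = k, gene = genes$gene_id[gi])
        }
      }
    }
  }
  if (length(hits) == 0) return(data.frame(peak = integer(0),
                                           gene = character(0)))
  unique(do.call(rbind, hits))
}

# two-sample permutation test on difference of means (B resamples)
perm_test_mean_diff <- function(a, b, B = 200, seed = 42) {
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  n1 <- length(a)
  set.seed(seed)
  hits <- 0
  for (i in seq_len(B)) {
    idx <- sample.int(length(pool), n1)
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs) hits <- hits + 1
  }
  (hits + 1) / (B + 1)
}

# exact null mean and sd of the signed-rank statistic W+ for the observed
# tie structure, by enumerating all 2^n sign assignments
enum_signed_rank <- function(x, y) {
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  w_null <- apply(combos, 1, function(s) sum(r[unlist(s)]))
  null_sd <- sqrt(mean((w_null - mean(w_null))^2)) # population sd
  list(z = (w_obs - mean(w_null)) / null_sd, n = n,
       w = w_obs, null_mean = mean(w_null), null_sd = null_sd)
}

# small random interval set on a single small chromosome
random_intervals <- function(n, chrom = "chrT", max_pos = 10000,
                             max_len = 800) {
  s <- sample.int(max_pos - max_len, n)
  data.frame(chrom = chrom, start = s,
             end = s + sample.int(max_len, n, replace = TRUE))
}
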