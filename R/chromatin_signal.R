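#' Fixed-bin genome-wide signal track
#'
#' Container for binned coverage (e.g. ChIP-seq) with an explicit
#' normalization state. `raw` tracks hold arbitrary non-negative counts;
#' `RPGC` (reads per genomic content, "1x depth") tracks have base-weighted
#' genome-wide mean exactly 1.
#'
#' @param values named list of per-chromosome numeric vectors, one value per
#'   bin; vector length must be `ceiling(chrom_length / bin_size)`.
#' @param bin_size bin width in bp.
#' @param chrom_lengths named chromosome lengths in bp.
#' @param normalization `"raw"` or `"RPGC"`.
#' @param mark,stage,replicate optional labels.
#' @return object of class `signal_track`.
#' @export
signal_track <- function(values, bin_size, chrom_lengths,
                         normalization = c("raw", "RPGC"),
                         mark = NA_character_, stage = NA_character_,
                         replicate = NA_integer_) {
  normalization <- match.arg(normalization)
  stopifnot(is.list(values), !is.null(names(values)),
            setequal(names(values), names(chrom_lengths)))
  for (ch in names(values)) {
    expect_len <- as.integer(ceiling(chrom_lengths[[ch]] / bin_size))
    if (length(values[[ch]]) != expect_len) {
      stop("track vector length for ", ch, " must be ", expect_len)
    }
    if (any(values[[ch]] < 0)) stop("track values must be non-negative")
  }
  structure(list(values = values[names(chrom_lengths)],
                 bin_size = as.integer(bin_size),
                 chrom_lengths = chrom_lengths,
                 normalization = normalization,
                 mark = mark, stage = stage, replicate = replicate),
            class = "signal_track")
}

# base-weighted genome-wide mean; last bin of a chromosome may be partial
.track_mean <- function(track) {
  tot <- 0
  bases <- 0
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    w <- rep(track$bin_size, length(v))
    w[length(w)] <- track$chrom_lengths[[ch]] - (length(v) - 1L) * track$bin_size
    tot <- tot + sum(v * w)
    bases <- bases + sum(w)
  }
  tot / bases
}

#' Normalize a raw track to 1x coverage (RPGC)
#'
#' Scales every bin by a single factor so that the base-weighted genome-wide
#' mean coverage equals 1 (reads per genomic content). Idempotent and
#' invariant to global rescaling of the raw counts.
#'
#' @param track a raw [signal_track()].
#' @param effective_genome_size optional; defaults to the sum of the track's
#'   chromosome lengths. The scaling uses mean coverage over this size.
#' @return the track with state `RPGC`.
#' @export
rpgc_normalize <- function(track, effective_genome_size = NULL) {
  stopifnot(inherits(track, "signal_track"))
  m <- .track_mean(track)
  if (m == 0) stop("cannot RPGC-normalize an all-zero track")
  if (!is.null(effective_genome_size)) {
    m <- m * sum(track$chrom_lengths) / effective_genome_size
  }
  track$values <- lapply(track$values, function(v) v / m)
  track$normalization <- "RPGC"
  track
}

#' Mean signal in fixed windows around regions
#'
#' For each region the mean track signal over the window
#' `[anchor - flank, anchor + flank)` is computed, where the anchor is the
#' region midpoint (`"center"`, the default, used for enhancers) or the
#' region start (`"start"`, used for TSS given as 1-bp features). Windows
#' are clipped at chromosome bounds and partial bins are weighted by their
#' base overlap.
#'
#' @param track a [signal_track()].
#' @param regions data.frame with chrom, start, end (BED convention).
#' @param flank half-window size in bp (default 1000, i.e. "within 1 kb").
#' @param anchor `"center"` or `"start"`.
#' @return numeric vector of per-region means (NA for zero-width windows).
#' @export
window_signal <- function(track, regions, flank = 1000L,
                          anchor = c("center", "start")) {
  stopifnot(inherits(track, "signal_track"))
  anchor <- match.arg(anchor)
  bad <- setdiff(unique(regions$chrom), names(track$chrom_lengths))
  if (length(bad)) stop("region on unknown chromosome: ", paste(bad, collapse = ", "))
  mid <- if (anchor == "center") {
    floor((regions$start + regions$end) / 2)
  } else {
    regions$start
  }
  ws <- pmax(mid - flank, 0)
  we <- pmin(mid + flank, track$chrom_lengths[regions$chrom])
  vapply(seq_len(nrow(regions)), function(i) {
    .window_mean(track, regions$chrom[i], ws[i], we[i])
  }, numeric(1))
}

.window_mean <- function(track, chrom, start, end) {
  if (end <= start) return(NA_real_)
  bs <- track$bin_size
  v <- track$values[[chrom]]
  b0 <- as.integer(start %/% bs)
  b1 <- as.integer((end - 1) %/% bs)
  idx <- (b0:b1) + 1L
  bin_starts <- (b0:b1) * bs
  w <- pmin(bin_starts + bs, end) - pmax(bin_starts, start)
  sum(v[idx] * w) / sum(w)
}

#' Classify enhancers into Group I / Group II by replicate stage ratios
#'
#' An enhancer whose EpiLC/EpiSC signal ratio exceeds `threshold` (strictly)
#' in at least `min_replicates` replicates is Group I (retains H3K4me1 in
#' EpiLC, i.e. only partially decommissioned); all others are Group II.
#' Ratios use a small pseudocount to guard against empty windows.
#'
#' @param window_means data.frame with columns enhancer_id, replicate,
#'   epilc, episc (per-enhancer window means per replicate).
#' @param threshold ratio threshold (default 1.2, strict `>`).
#' @param min_replicates replicates required above threshold (default 2).
#' @param pseudocount added to numerator and denominator (default 0.01,
#'   negligible against RPGC signal of order 1).
#' @return data.frame: enhancer_id, one `ratio_rep<i>` column per replicate,
#'   n_pass, group (`"I"`/`"II"`).
#' @export
classify_groups <- function(window_means, threshold = 1.2,
                            min_replicates = 2L, pseudocount = 0.01) {
  need <- c("enhancer_id", "replicate", "epilc", "episc")
  stopifnot(all(need %in% names(window_means)))
  dt <- data.table::as.data.table(window_means)
  reps <- sort(unique(dt$replicate))
  ids <- unique(dt$enhancer_id)
  cnt <- dt[, .N, by = "enhancer_id"]
  if (any(cnt$N != length(reps))) {
    stop("missing replicate data for enhancer(s): ",
         paste(utils::head(cnt$enhancer_id[cnt$N != length(reps)], 5),
               collapse = ", "))
  }
  dt$ratio <- (dt$epilc + pseudocount) / (dt$episc + pseudocount)
  wide <- data.table::dcast(dt, enhancer_id ~ replicate, value.var = "ratio")
  data.table::setnames(wide, as.character(reps),
                       paste0("ratio_rep", reps))
  rmat <- as.matrix(wide[, -1, with = FALSE])
  n_pass <- rowSums(rmat > threshold)
  out <- as.data.frame(wide)
  out$n_pass <- as.integer(n_pass)
  out$group <- ifelse(n_pass >= min_replicates, "I", "II")
  out <- out[match(ids, out$enhancer_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Wilcoxon signed-rank z statistic: zero differences dropped, average ranks,
# tie-corrected variance, no continuity correction. Returns z and the number
# of non-zero pairs.
.signed_rank_z <- function(x, y) {
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(z = NA_real_, n = 0L))
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  list(z = (w_pos - mu) / sqrt(sigma2), n = n)
}

#' Paired signed-rank effect size r = z / sqrt(n)
#'
#' Effect size of a paired two-sided Wilcoxon signed-rank comparison between
#' two stages, computed as the normal-approximation z statistic divided by
#' the square root of the number of informative (non-zero-difference) pairs.
#' Positive r means `y` (stage B) exceeds `x` (stage A). A percentile
#' bootstrap over resampled pairs gives the confidence interval.
#'
#' @param x,y equal-length numeric vectors of per-enhancer values in the two
#'   stages (paired by position).
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return list with `z`, `n`, `r`, `ci` (length-2), `conf`.
#' @export
paired_effect_size <- function(x, y, n_boot = 1000L, conf = 0.95,
                               seed = 1L) {
  stopifnot(length(x) == length(y), length(x) >= 10)
  obs <- .signed_rank_z(x, y)
  if (obs$n == 0) {
    warning("all paired differences are zero; effect size reported as 0")
    return(list(z = 0, n = 0L, r = 0, ci = c(0, 0), conf = conf))
  }
  clamp <- function(r) pmin(1, pmax(-1, r)) # exact-tie cases hit +/-1
  r_obs <- clamp(obs$z / sqrt(obs$n))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(x), replace = TRUE)
      bz <- .signed_rank_z(x[idx], y[idx])
      if (bz$n == 0) 0 else clamp(bz$z / sqrt(bz$n))
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boot, c(alpha, 1 - alpha), type = 7))
  list(z = obs$z, n = obs$n, r = r_obs, ci = ci, conf = conf)
}

#' Flanking-bin methylation vs H3K4me1 correlation
#'
#' For each enhancer, the mean of each signal is computed in one 500 bp bin
#' immediately upstream and one immediately downstream of the enhancer
#' interval; the two bin means are averaged per enhancer, and the Spearman
#' correlation of the two pooled means across enhancers is returned.
#'
#' @param meth_track,h3k4me1_track [signal_track()]s on the same genome
#'   (units are irrelevant to the rank correlation).
#' @param enhancers data.frame with chrom, start, end.
#' @param bin flank bin width in bp (default 500).
#' @return list with `rho` and `per_enhancer` (meth, h3k4me1 pooled means).
#' @export
flank_methylation_correlation <- function(meth_track, h3k4me1_track,
                                          enhancers, bin = 500L) {
  pooled <- function(track) {
    vapply(seq_len(nrow(enhancers)), function(i) {
      ch <- enhancers$chrom[i]
      len <- track$chrom_lengths[[ch]]
      up <- c(max(enhancers$start[i] - bin, 0), enhancers$start[i])
      dn <- c(enhancers$end[i], min(enhancers$end[i] + bin, len))
      vals <- c(if (up[2] > up[1]) .window_mean(track, ch, up[1], up[2]),
                if (dn[2] > dn[1]) .window_mean(track, ch, dn[1], dn[2]))
      if (length(vals) == 0) NA_real_ else mean(vals)
    }, numeric(1))
  }
  m <- pooled(meth_track)
  k <- pooled(h3k4me1_track)
  ok <- stats::complete.cases(m, k)
  if (sum(ok) < 3) stop("fewer than 3 enhancers with both signals defined")
  rho <- stats::cor(m[ok], k[ok], method = "spearman")
  list(rho = rho,
       per_enhancer = data.frame(meth = m, h3k4me1 = k))
}
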