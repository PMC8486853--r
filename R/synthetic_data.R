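#' Simulation configuration for the synthetic germline-competence data set
#'
#' Bundles every knob of the synthetic-data generators. One master integer
#' seed determines all outputs; each generator draws from an independent
#' substream (`seed` + a fixed offset) so adding, say, a replicate never
#' perturbs the other data types.
#'
#' Defaults emulate the shapes of the study's inputs at toy scale: a
#' two-chromosome 1 Mb genome with 100 bp bins, three H3K4me1 replicates in
#' EpiLC and EpiSC with a planted set of enhancers whose EpiLC/EpiSC
#' fold-change is 2.0 (class I) or 1.0 (class II), capture Hi-C style anchor
#' pairs linking each true enhancer to its target gene TSS, stage-labelled
#' negative-binomial UMI counts with a rare PGCLC-like cluster, and sparse
#' single-cell CpG methylomes whose per-stage beta variance plants a known
#' heterogeneity ordering.
#'
#' @param seed master integer seed.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param bin_size signal-track bin width (bp); must divide every length.
#' @param n_genes number of gene models.
#' @param n_class1,n_class2,n_decoy enhancers per truth class. Decoy
#'   enhancers are distal peaks that are never linked to a gene.
#' @param enhancer_width enhancer interval width (bp); kept at 2 kb so the
#'   default 1 kb quantification window sits entirely inside the enhancer
#'   and zero-noise ratios are analytically exact.
#' @param fold_class1 true EpiLC/EpiSC H3K4me1 fold for class I (> the 1.2
#'   classifier threshold).
#' @param fold_class2 true fold for class II (1.0 = no change).
#' @param enhancer_signal,baseline_signal raw track means inside enhancers
#'   and in background bins.
#' @param noise_sd standard deviation of the multiplicative lognormal
#'   replicate noise on enhancer signal.
#' @param n_replicates ChIP replicates per stage.
#' @param n_decoy_pairs interaction pairs violating a distance rule.
#' @param umi list of scRNA-seq simulation parameters (gene/cluster sizes,
#'   marker effect, per-stage NB dispersion).
#' @param meth list of single-cell methylome parameters (cells and beta
#'   variance per stage, CpGs per enhancer, site dropout, read depth range).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 1000000L, chr2 = 1000000L),
                       bin_size = 100L,
                       n_genes = 50L,
                       n_class1 = 40L,
                       n_class2 = 40L,
                       n_decoy = 20L,
                       enhancer_width = 2000L,
                       fold_class1 = 2.0,
                       fold_class2 = 1.0,
                       enhancer_signal = 8,
                       baseline_signal = 0.5,
                       noise_sd = 0.1,
                       n_replicates = 3L,
                       n_decoy_pairs = 40L,
                       umi = list(),
                       meth = list()) {
  umi_def <- list(
    n_genes = 500L,
    n_markers = 20L,
    marker_fold = 4,
    marker_off = 0.3,
    klf4_on = 4,
    klf4_off = 0.02,
    base_mu = 2,
    gene_lsd = 0.5,
    stages = c(ESC = 80L, EpiLC = 80L, EpiSC = 80L),
    stage_dispersion = c(ESC = 0.8, EpiLC = 0.2, EpiSC = 0.8),
    eb_clusters = c(PGCLC = 40L, ExEctoderm = 60L, ExMesoderm = 60L,
                    Endothelial = 40L),
    eb_dispersion = 0.5
  )
  meth_def <- list(
    stage_cells = c(E4.5 = 12L, E5.5 = 12L, E6.5 = 12L),
    stage_var = c(E4.5 = 0.01, E5.5 = 0.09, E6.5 = 0.04),
    mean_level = 0.5,
    n_cpg_per_enh = 20L,
    dropout = 0.3,
    depth_range = c(3L, 30L)
  )
  umi <- utils::modifyList(umi_def, umi)
  meth <- utils::modifyList(meth_def, meth)

  cfg <- list(
    seed = as.integer(seed), chrom_lengths = chrom_lengths,
    bin_size = as.integer(bin_size), n_genes = as.integer(n_genes),
    n_class1 = as.integer(n_class1), n_class2 = as.integer(n_class2),
    n_decoy = as.integer(n_decoy), enhancer_width = as.integer(enhancer_width),
    fold_class1 = fold_class1, fold_class2 = fold_class2,
    enhancer_signal = enhancer_signal, baseline_signal = baseline_signal,
    noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
    n_decoy_pairs = as.integer(n_decoy_pairs), umi = umi, meth = meth
  )
  stopifnot(length(cfg$seed) == 1, !is.na(cfg$seed))
  if (any(chrom_lengths %% bin_size != 0)) {
    stop("bin_size must divide every chromosome length")
  }
  if (fold_class1 <= 1.2) {
    stop("fold_class1 must exceed the downstream classifier threshold (1.2)")
  }
  structure(cfg, class = "sim_config")
}

# fixed substream offsets (kept < 2^31 when added to any small master seed)
.seed_offsets <- c(genome = 1000L, tracks = 2000L, interactions = 3000L,
                   umi = 4000L, meth = 5000L)

#' Generate a synthetic genome with planted enhancer truth
#'
#' Places gene models and disjoint enhancer intervals on the configured
#' chromosomes. Enhancers are kept at least 4 kb from every TSS so the
#' promoter-proximity rules downstream (3.5 kb minimum TSS distance,
#' TSS +/- 2 kb promoter mask) are exercised non-trivially, and their starts
#' are snapped to the bin grid so zero-noise window means are exact.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_genome`: list with `chrom_lengths`,
#'   `genes` (gene_id, name, chrom, tss, strand) and `enhancers` (chrom,
#'   start, end, enhancer_id, class in I/II/decoy, target_gene).
#' @export
gen_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_enh <- config$n_class1 + config$n_class2 + config$n_decoy
  if (n_enh * (config$enhancer_width + 200) > sum(config$chrom_lengths)) {
    stop("enhancer set cannot fit disjointly on the configured genome")
  }
  with_seed(config$seed + .seed_offsets[["genome"]], {
    chroms <- names(config$chrom_lengths)
    # gene models: TSS at least 12 kb apart so capture Hi-C anchors placed
    # near one TSS can never satisfy the 3 kb rule at a neighbouring one
    gene_chrom <- character(config$n_genes)
    tss <- integer(config$n_genes)
    tss_by_chrom <- stats::setNames(vector("list", length(chroms)), chroms)
    gi <- 1L
    tries <- 0L
    while (gi <= config$n_genes) {
      tries <- tries + 1L
      if (tries > 200L * config$n_genes) {
        stop("could not place ", config$n_genes, " well-separated genes")
      }
      ch <- sample(chroms, 1L,
                   prob = config$chrom_lengths / sum(config$chrom_lengths))
      len <- config$chrom_lengths[[ch]]
      t <- sample.int(len - 20000L, 1L) + 10000L
      if (length(tss_by_chrom[[ch]]) &&
          any(abs(tss_by_chrom[[ch]] - t) < 12000L)) next
      tss_by_chrom[[ch]] <- c(tss_by_chrom[[ch]], t)
      gene_chrom[gi] <- ch
      tss[gi] <- t
      gi <- gi + 1L
    }
    genes <- data.frame(
      gene_id = sprintf("g%03d", seq_len(config$n_genes)),
      name = sprintf("Gene%03d", seq_len(config$n_genes)),
      chrom = gene_chrom, tss = tss,
      strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
      stringsAsFactors = FALSE
    )
    # enhancer placement: rejection sampling, >= 4 kb from every TSS,
    # >= 4 kb gap between enhancers (keeps flanking bins and anchor
    # neighbourhoods disjoint), starts on the bin grid
    w <- config$enhancer_width
    placed <- vector("list", n_enh)
    occupied <- lapply(chroms, function(ch) genes$tss[genes$chrom == ch])
    names(occupied) <- chroms
    enh_by_chrom <- lapply(chroms, function(ch) matrix(numeric(0), ncol = 2))
    names(enh_by_chrom) <- chroms
    max_tries <- 200L * n_enh
    tries <- 0L
    i <- 1L
    while (i <= n_enh) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("could not place ", n_enh, " disjoint enhancers; genome too small")
      }
      ch <- sample(chroms, 1L,
                   prob = config$chrom_lengths / sum(config$chrom_lengths))
      len <- config$chrom_lengths[[ch]]
      start <- (sample.int((len - w) %/% config$bin_size, 1L) - 1L) *
        config$bin_size
      end <- start + w
      # clearance to TSSs (4 kb beyond either edge)
      tss_ch <- occupied[[ch]]
      if (length(tss_ch) && any(tss_ch > start - 4000 & tss_ch < end + 4000)) next
      prev <- enh_by_chrom[[ch]]
      if (nrow(prev) && any(prev[, 1] < end + 4000 & prev[, 2] > start - 4000)) next
      enh_by_chrom[[ch]] <- rbind(prev, c(start, end))
      placed[[i]] <- data.frame(chrom = ch, start = start, end = end,
                                stringsAsFactors = FALSE)
      i <- i + 1L
    }
    enh <- do.call(rbind, placed)
    cls <- c(rep("I", config$n_class1), rep("II", config$n_class2),
             rep("decoy", config$n_decoy))
    target <- rep(NA_character_, n_enh)
    linked <- cls != "decoy"
    target[linked] <- sample(genes$gene_id, sum(linked), replace = TRUE)
    enh$enhancer_id <- sprintf("enh%03d", seq_len(n_enh))
    enh$class <- cls
    enh$target_gene <- target
    enh <- enh[order(enh$chrom, enh$start), , drop = FALSE]
    rownames(enh) <- NULL
    structure(list(chrom_lengths = config$chrom_lengths, genes = genes,
                   enhancers = enh),
              class = "synthetic_genome")
  })
}

#' Generate raw multi-replicate histone-mark signal tracks
#'
#' Builds fixed-bin H3K4me1 tracks for EpiLC and EpiSC. Background bins sit
#' at a low baseline with per-bin lognormal noise; enhancer bins carry a
#' high mean, multiplied in EpiLC by the planted class fold (class I:
#' `fold_class1`; class II and decoys: `fold_class2`). Replicate noise is a
#' single multiplicative lognormal factor per (enhancer, stage, replicate),
#' so the windowed EpiLC/EpiSC ratio of a class-I enhancer is distributed
#' `fold * exp(N(0, noise_sd * sqrt(2)))` and equals the fold exactly at
#' `noise_sd = 0`.
#'
#' @param genome a [gen_genome()] result.
#' @param config the matching [sim_config()].
#' @return named list of raw [signal_track()]s, names `H3K4me1_<stage>_rep<i>`.
#' @export
gen_signal_tracks <- function(genome, config) {
  stopifnot(inherits(genome, "synthetic_genome"))
  stages <- c("EpiLC", "EpiSC")
  out <- list()
  for (si in seq_along(stages)) {
    for (rep_i in seq_len(config$n_replicates)) {
      sub_seed <- config$seed + .seed_offsets[["tracks"]] +
        100L * si + rep_i
      out[[sprintf("H3K4me1_%s_rep%d", stages[si], rep_i)]] <-
        with_seed(sub_seed, {
          .build_track(genome, config, stages[si], rep_i)
        })
    }
  }
  out
}

.build_track <- function(genome, config, stage, rep_i) {
  bs <- config$bin_size
  values <- lapply(names(genome$chrom_lengths), function(ch) {
    n_bins <- genome$chrom_lengths[[ch]] %/% bs
    v <- config$baseline_signal *
      exp(rnorm(n_bins, 0, config$noise_sd))
    v
  })
  names(values) <- names(genome$chrom_lengths)
  enh <- genome$enhancers
  fold <- ifelse(enh$class == "I", config$fold_class1, config$fold_class2)
  stage_mult <- if (stage == "EpiLC") fold else rep(1, nrow(enh))
  enh_noise <- exp(rnorm(nrow(enh), 0, config$noise_sd))
  for (k in seq_len(nrow(enh))) {
    b0 <- enh$start[k] %/% bs + 1L
    b1 <- (enh$end[k] - 1L) %/% bs + 1L
    values[[enh$chrom[k]]][b0:b1] <-
      config$enhancer_signal * stage_mult[k] * enh_noise[k]
  }
  signal_track(values, bin_size = bs, chrom_lengths = genome$chrom_lengths,
               normalization = "raw", mark = "H3K4me1", stage = stage,
               replicate = rep_i)
}

#' Generate capture Hi-C style interaction pairs
#'
#' Emits one true anchor pair per linked (class I/II) enhancer: one anchor
#' overlapping or within 1 kb of the enhancer, the partner anchor within
#' 3 kb of the target gene TSS. Decoy pairs violate the peak-distance or the
#' TSS-distance rule by a wide margin (>= 5 kb clearance from every enhancer
#' or every TSS), so a correct linker must recover all true pairs and no
#' decoys. Anchor order is randomized to exercise order symmetry.
#'
#' @inheritParams gen_signal_tracks
#' @return data.frame in BEDPE column order (chrom1, start1, end1, chrom2,
#'   start2, end2, name, label) with `label` in `true`/`decoy`.
#' @export
gen_interactions <- function(genome, config) {
  stopifnot(inherits(genome, "synthetic_genome"))
  with_seed(config$seed + .seed_offsets[["interactions"]], {
    enh <- genome$enhancers[genome$enhancers$class != "decoy", , drop = FALSE]
    genes <- genome$genes
    aw <- 500L # anchor width
    true_pairs <- lapply(seq_len(nrow(enh)), function(k) {
      g <- genes[genes$gene_id == enh$target_gene[k], ]
      # anchor on the enhancer: start within [-500, width-500] of enhancer start
      off <- sample.int(enh$end[k] - enh$start[k] + 500L, 1L) - 501L
      a1s <- max(0L, enh$start[k] + off)
      # anchor near the TSS: fully within +/- 2.5 kb
      toff <- sample.int(5000L - aw, 1L) - 2500L
      a2s <- max(0L, g$tss + toff)
      data.frame(chrom1 = enh$chrom[k], start1 = a1s, end1 = a1s + aw,
                 chrom2 = g$chrom, start2 = a2s, end2 = a2s + aw,
                 name = enh$enhancer_id[k], label = "true",
                 stringsAsFactors = FALSE)
    })
    decoys <- lapply(seq_len(config$n_decoy_pairs), function(k) {
      # far anchor: >= 5 kb from every enhancer and every TSS
      far <- .sample_clear_position(genome, aw, clearance = 5000L)
      if (k %% 2 == 0 && nrow(enh)) {
        # near a real enhancer but partnered with a far anchor (TSS rule fails)
        e <- enh[sample.int(nrow(enh), 1L), ]
        a1 <- c(e$chrom, e$start, e$start + aw)
      } else {
        a1 <- .sample_clear_position(genome, aw, clearance = 5000L)
      }
      data.frame(chrom1 = a1[[1]], start1 = as.integer(a1[[2]]),
                 end1 = as.integer(a1[[3]]),
                 chrom2 = far[[1]], start2 = as.integer(far[[2]]),
                 end2 = as.integer(far[[3]]),
                 name = sprintf("decoy%03d", k), label = "decoy",
                 stringsAsFactors = FALSE)
    })
    pairs <- rbind(do.call(rbind, true_pairs), do.call(rbind, decoys))
    # randomize anchor order for half the pairs
    flip <- runif(nrow(pairs)) < 0.5
    flipped <- pairs[flip, c(4:6, 1:3, 7:8)]
    names(flipped) <- names(pairs)
    pairs[flip, ] <- flipped
    rownames(pairs) <- NULL
    pairs
  })
}

# sample an anchor-sized interval >= `clearance` bp from every enhancer edge
# and TSS; rejection sampling
.sample_clear_position <- function(genome, width, clearance) {
  chroms <- names(genome$chrom_lengths)
  for (try in 1:10000) {
    ch <- sample(chroms, 1L)
    len <- genome$chrom_lengths[[ch]]
    s <- sample.int(len - width, 1L)
    e <- s + width
    enh <- genome$enhancers[genome$enhancers$chrom == ch, ]
    tss <- genome$genes$tss[genome$genes$chrom == ch]
    if (nrow(enh) && any(enh$start < e + clearance & enh$end > s - clearance)) next
    if (length(tss) && any(tss > s - clearance & tss < e + clearance)) next
    return(list(ch, s, e))
  }
  stop("could not find a clear decoy-anchor position")
}

#' Generate a stage- and cluster-labelled UMI count matrix
#'
#' Negative-binomial counts for three pluripotent stages (ESC, EpiLC, EpiSC)
#' plus a d4-embryoid-body compartment split into clusters, one of which is
#' a rare PGCLC-like cluster over-expressing a designated marker set. The
#' gating genes Dppa3 and Prdm1 are PGCLC markers; Klf4 is expressed in
#' every non-PGCLC cell. EpiLC is generated with a lower NB dispersion than
#' ESC/EpiSC so the downstream transcriptional-noise statistic ranks it
#' lowest by construction. A 2-D blob embedding (one Gaussian blob per EB
#' cluster) is attached for the clustering stage.
#'
#' @param config a [sim_config()]; parameters under `config$umi`.
#' @return object of class `umi_counts`: list with `counts` (genes x cells
#'   integer matrix), `cell_meta` (cell_id, stage, cluster, emb1, emb2) and
#'   `marker_sets` (named list of planted marker genes per EB cluster).
#' @export
gen_umi_matrix <- function(config) {
  u <- config$umi
  with_seed(config$seed + .seed_offsets[["umi"]], {
    clusters <- names(u$eb_clusters)
    marker_sets <- lapply(clusters, function(cl) {
      sprintf("%s_mk%02d", cl, seq_len(u$n_markers))
    })
    names(marker_sets) <- clusters
    if ("PGCLC" %in% clusters) {
      marker_sets$PGCLC[1:2] <- c("Dppa3", "Prdm1")
    }
    marker_genes <- unlist(marker_sets, use.names = FALSE)
    n_null <- max(0L, u$n_genes - length(marker_genes) - 1L)
    genes <- c(marker_genes, "Klf4", sprintf("null%03d", seq_len(n_null)))

    stage_cells <- data.frame(
      cell_id = character(0), stage = character(0), cluster = character(0),
      stringsAsFactors = FALSE)
    for (st in names(u$stages)) {
      n <- u$stages[[st]]
      stage_cells <- rbind(stage_cells, data.frame(
        cell_id = sprintf("%s_c%03d", st, seq_len(n)), stage = st,
        cluster = st, stringsAsFactors = FALSE))
    }
    for (cl in clusters) {
      n <- u$eb_clusters[[cl]]
      stage_cells <- rbind(stage_cells, data.frame(
        cell_id = sprintf("EB_%s_c%03d", cl, seq_len(n)), stage = "d4EB",
        cluster = cl, stringsAsFactors = FALSE))
    }
    n_cells <- nrow(stage_cells)

    # gene baseline means, shared across cells: null genes vary
    # lognormally around base_mu; marker genes sit at a low off-state
    # everywhere except their own cluster (off * fold); Klf4 is on in every
    # cell except the PGCLC cluster
    mu_g <- u$base_mu * exp(rnorm(length(genes), 0, u$gene_lsd))
    names(mu_g) <- genes
    mu_g[marker_genes] <- u$marker_off
    mu_g["Klf4"] <- u$klf4_on
    counts <- matrix(0L, nrow = length(genes), ncol = n_cells,
                     dimnames = list(genes, stage_cells$cell_id))
    for (j in seq_len(n_cells)) {
      cl <- stage_cells$cluster[j]
      st <- stage_cells$stage[j]
      mu <- mu_g
      if (cl %in% clusters) {
        mu[marker_sets[[cl]]] <- u$marker_off * u$marker_fold
        if (cl == "PGCLC") mu["Klf4"] <- u$klf4_off
      }
      disp <- if (st %in% names(u$stage_dispersion)) {
        u$stage_dispersion[[st]]
      } else {
        u$eb_dispersion
      }
      counts[, j] <- if (disp > 0) {
        rnbinom(length(mu), mu = mu, size = 1 / disp)
      } else {
        stats::rpois(length(mu), mu)
      }
    }

    # blob embedding for EB cells (one blob per cluster); stage cells get
    # their own blobs so k-means fixtures can use any subset
    all_groups <- unique(stage_cells$cluster)
    theta <- seq(0, 2 * pi, length.out = length(all_groups) + 1)[-1]
    centers <- cbind(10 * cos(theta), 10 * sin(theta))
    rownames(centers) <- all_groups
    emb <- centers[stage_cells$cluster, , drop = FALSE] +
      matrix(rnorm(2 * n_cells, 0, 0.5), ncol = 2)
    stage_cells$emb1 <- emb[, 1]
    stage_cells$emb2 <- emb[, 2]
    structure(list(counts = counts, cell_meta = stage_cells,
                   marker_sets = marker_sets),
              class = "umi_counts")
  })
}

#' Generate sparse single-cell CpG methylomes with planted heterogeneity
#'
#' For each stage, each cell draws one methylation level per enhancer from a
#' beta distribution with mean `meth$mean_level` and the stage's variance
#' (`meth$stage_var`); per-CpG read counts are binomial given the level, and
#' sites drop out independently per cell (Bernoulli `meth$dropout`). CpG
#' site positions are shared across cells (evenly spaced within each linked
#' enhancer) so pairwise shared-site structure is realistic. A stage with
#' variance 0 gives every cell the identical level, so downstream pairwise
#' dissimilarity reflects binomial sampling noise only.
#'
#' @inheritParams gen_signal_tracks
#' @return list with `calls` (data.table: cell_id, chrom, pos, meth_count,
#'   total_count), `cell_meta` (cell_id, stage) and `sites` (chrom, pos,
#'   enhancer_id).
#' @export
gen_methylomes <- function(genome, config) {
  m <- config$meth
  enh <- genome$enhancers[genome$enhancers$class != "decoy", , drop = FALSE]
  with_seed(config$seed + .seed_offsets[["meth"]], {
    sites <- do.call(rbind, lapply(seq_len(nrow(enh)), function(k) {
      pos <- as.integer(round(seq(enh$start[k] + 10, enh$end[k] - 10,
                                  length.out = m$n_cpg_per_enh)))
      data.frame(chrom = enh$chrom[k], pos = pos,
                 enhancer_id = enh$enhancer_id[k], stringsAsFactors = FALSE)
    }))
    cell_meta <- do.call(rbind, lapply(names(m$stage_cells), function(st) {
      data.frame(cell_id = sprintf("%s_cell%03d", st,
                                   seq_len(m$stage_cells[[st]])),
                 stage = st, stringsAsFactors = FALSE)
    }))
    mu <- m$mean_level
    calls <- vector("list", nrow(cell_meta))
    for (ci in seq_len(nrow(cell_meta))) {
      v <- m$stage_var[[cell_meta$stage[ci]]]
      if (v > 0) {
        conc <- mu * (1 - mu) / v - 1
        if (conc <= 0) stop("stage variance too large for beta model")
        levels <- rbeta(nrow(enh), mu * conc, (1 - mu) * conc)
      } else {
        levels <- rep(mu, nrow(enh))
      }
      names(levels) <- enh$enhancer_id
      covered <- runif(nrow(sites)) >= m$dropout
      s <- sites[covered, , drop = FALSE]
      tot <- sample(seq(m$depth_range[1], m$depth_range[2]),
                    nrow(s), replace = TRUE)
      met <- rbinom(nrow(s), tot, levels[s$enhancer_id])
      calls[[ci]] <- data.table::data.table(
        cell_id = cell_meta$cell_id[ci], chrom = s$chrom, pos = s$pos,
        meth_count = met, total_count = tot)
    }
    list(calls = data.table::rbindlist(calls), cell_meta = cell_meta,
         sites = sites)
  })
}

#' Write the full synthetic data set to disk
#'
#' Serializes every generated object in its standard plain-text format
#' (BED, bedGraph, BEDPE, TSV) and writes a JSON manifest listing all paths
#' and the truth tables.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest list (also written as `manifest.json`).
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- gen_genome(config)
  tracks <- gen_signal_tracks(genome, config)
  pairs <- gen_interactions(genome, config)
  umi <- gen_umi_matrix(config)
  meth <- gen_methylomes(genome, config)

  p <- function(...) file.path(dir, ...)
  fwrite_tsv <- function(x, path) {
    data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  }
  fwrite_tsv(genome$genes, p("genes.tsv"))
  write_bed(genome$enhancers[, c("chrom", "start", "end", "enhancer_id")],
            p("peaks.bed"))
  fwrite_tsv(genome$enhancers, p("enhancer_truth.tsv"))
  data.table::fwrite(
    data.frame(chrom = names(genome$chrom_lengths),
               length = unname(genome$chrom_lengths)),
    p("chrom_sizes.tsv"), sep = "\t", quote = FALSE, col.names = FALSE)
  track_paths <- character(0)
  for (nm in names(tracks)) {
    path <- p(paste0(nm, ".bedGraph"))
    write_bedgraph(tracks[[nm]], path)
    track_paths[nm] <- path
  }
  write_bedpe(pairs, p("interactions.bedpe"))
  fwrite_tsv(data.table::data.table(gene = rownames(umi$counts),
                                    umi$counts), p("umi_counts.tsv"))
  fwrite_tsv(umi$cell_meta, p("umi_cell_meta.tsv"))
  fwrite_tsv(meth$calls, p("meth_calls.tsv"))
  fwrite_tsv(meth$cell_meta, p("meth_cell_meta.tsv"))

  manifest <- list(
    config = unclass(config),
    paths = c(list(
      genes = p("genes.tsv"), peaks = p("peaks.bed"),
      enhancer_truth = p("enhancer_truth.tsv"),
      chrom_sizes = p("chrom_sizes.tsv"),
      interactions = p("interactions.bedpe"),
      umi_counts = p("umi_counts.tsv"), umi_cell_meta = p("umi_cell_meta.tsv"),
      meth_calls = p("meth_calls.tsv"), meth_cell_meta = p("meth_cell_meta.tsv")
    ), as.list(track_paths))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
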