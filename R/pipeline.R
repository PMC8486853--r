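#' Pipeline configuration with field-standard defaults
#'
#' Collects every tunable threshold of the pipeline, each defaulting to the
#' value used throughout this package's analyses: 1 kb peak-merge gap, 2 kb
#' promoter flank, 1 kb anchor-to-peak and 3 kb anchor-to-TSS linking
#' distances, 500 kb proximal window with 3.5 kb minimum TSS distance, 1 kb
#' quantification flank, 1.2 ratio threshold in >= 2 replicates, gene-set
#' thresholds padj < 0.005 / pct.1 > 0.2 / pct.2 < 0.4, gating thresholds
#' 0.1 / 1 / 1, CpG coverage 3-100 with > 100 sites per cell, 500 variable
#' genes, 1000 bootstrap resamples.
#'
#' @param seed master seed; also seeds the synthetic data when simulating.
#' @param sim a [sim_config()] for the synthetic demo; when NULL the paths
#'   in `paths` must point at existing inputs.
#' @param paths named list of input paths (as written by
#'   [simulate_dataset()]); ignored when `sim` is given.
#' @param out_dir output directory.
#' @param thresholds named list overriding any default listed above.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = NULL, paths = NULL,
                            out_dir = tempfile("germcomp_run_"),
                            thresholds = list()) {
  def <- list(
    gap = 1000L, promoter_flank = 2000L, peak_dist = 1000L,
    tss_dist = 3000L, max_dist = 500000L, min_tss_dist = 3500L,
    flank = 1000L, ratio_threshold = 1.2, min_replicates = 2L,
    pseudocount = 0.01, padj = 0.005, pct1_min = 0.2, pct2_max = 0.4,
    gate_dppa3 = 0.1, gate_prdm1 = 1, gate_klf4 = 1,
    min_cov = 3L, max_cov = 100L, min_sites = 100L,
    n_variable_genes = 500L, n_boot = 1000L
  )
  unknown <- setdiff(names(thresholds), names(def))
  if (length(unknown)) stop("unknown threshold(s): ",
                            paste(unknown, collapse = ", "))
  thr <- utils::modifyList(def, thresholds)
  if (any(vapply(thr, function(x) !is.numeric(x) || x <= 0, logical(1)))) {
    stop("all thresholds must be positive numbers")
  }
  structure(list(seed = as.integer(seed), sim = sim, paths = paths,
                 out_dir = out_dir, thresholds = thr),
            class = "pipeline_config")
}

.stage_fail <- function(stage, msg) {
  stop(sprintf("[stage %s] %s", stage, msg), call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic-data generation (when the config carries a
#' [sim_config()]), gene-set definition and PGCLC gating from the UMI
#' matrix, enhancer-catalog construction (merge, promoter subtraction,
#' interaction linking), RPGC normalization with windowed quantification
#' and Group I/II classification plus the paired effect size, and
#' single-cell methylation heterogeneity. Each stage writes its outputs
#' under `out_dir` and a JSON manifest records the config, paths and row
#' counts. Reruns with the same config and seed are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list (also in `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  thr <- config$thresholds
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(stage, what) {
    line <- sprintf("%s\t%s", stage, what)
    message("[germcomp] ", line)
    log_lines <<- c(log_lines, line)
  }

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$sim)) {
    sim_dir <- file.path(out, "sim")
    manifest_sim <- simulate_dataset(config$sim, sim_dir)
    paths <- manifest_sim$paths
    note("simulate", sprintf("generated synthetic data in %s", sim_dir))
  } else {
    paths <- config$paths
    if (is.null(paths)) .stage_fail("inputs", "no sim config and no paths")
  }
  need <- c("genes", "peaks", "interactions", "umi_counts", "umi_cell_meta",
            "meth_calls", "meth_cell_meta", "chrom_sizes")
  for (nm in need) {
    if (is.null(paths[[nm]]) || !file.exists(paths[[nm]])) {
      .stage_fail(if (nm == "peaks") "catalog" else "inputs",
                  sprintf("missing input '%s': %s", nm,
                          paths[[nm]] %||% "<unset>"))
    }
  }
  cs <- data.table::fread(paths$chrom_sizes, header = FALSE,
                          col.names = c("chrom", "length"))
  chrom_lengths <- stats::setNames(cs$length, cs$chrom)
  genes <- as.data.frame(data.table::fread(paths$genes))
  umi <- read_umi_matrix(paths$umi_counts, paths$umi_cell_meta)

  # --- gene sets & gating -------------------------------------------------
  meta <- umi$cell_meta
  pg_cells <- meta$cell_id[meta$cluster == "PGCLC"]
  eb_other <- meta$cell_id[meta$stage == "d4EB" & meta$cluster != "PGCLC"]
  if (length(pg_cells) == 0 || length(eb_other) == 0) {
    .stage_fail("genesets", "no PGCLC cluster in cell metadata")
  }
  gs <- define_gene_set(umi, pg_cells, eb_other, padj = thr$padj,
                        pct1_min = thr$pct1_min, pct2_max = thr$pct2_max)
  data.table::fwrite(gs$table, file.path(out, "pgclc_gene_set.tsv"),
                     sep = "\t")
  note("genesets", sprintf("%d member genes of %d tested",
                           length(gs$members), nrow(gs$table)))
  gated <- gate_pgclc_cells(umi, dppa3 = thr$gate_dppa3,
                            prdm1 = thr$gate_prdm1, klf4 = thr$gate_klf4)
  writeLines(gated, file.path(out, "gated_cells.txt"))
  note("gate", sprintf("%d cells gated in", length(gated)))

  noise <- lapply(c("ESC", "EpiLC", "EpiSC"), function(st) {
    nr <- transcriptional_noise(umi, st,
                                n_variable_genes = thr$n_variable_genes)
    data.frame(stage = st, median_d = median(nr$pairs$d))
  })
  noise <- do.call(rbind, noise)
  data.table::fwrite(noise, file.path(out, "transcriptional_noise.tsv"),
                     sep = "\t")
  note("noise", paste(sprintf("%s=%.4f", noise$stage, noise$median_d),
                      collapse = " "))

  # --- enhancer catalog ---------------------------------------------------
  peaks <- tryCatch(read_bed(paths$peaks, extra_names = "peak_id"),
                    error = function(e) .stage_fail("catalog", conditionMessage(e)))
  merged <- merge_peaks(peaks, gap_bp = thr$gap)
  distal <- subtract_regions(
    merged, promoter_mask(genes, flank = thr$promoter_flank,
                          chrom_lengths = chrom_lengths))
  interactions <- read_bedpe(paths$interactions)
  records <- link_enhancers(distal, interactions, genes,
                            peak_dist = thr$peak_dist,
                            tss_dist = thr$tss_dist)
  data.table::fwrite(records, file.path(out, "enhancer_catalog.tsv"),
                     sep = "\t")
  epg <- if (nrow(records)) enhancers_per_gene(records) else NA_real_
  note("catalog", sprintf("%d peaks -> %d distal -> %d linked (%.1f enh/gene)",
                          nrow(peaks), nrow(distal), nrow(records), epg))

  # --- chromatin quantification & classification --------------------------
  track_names <- grep("^H3K4me1_", names(paths), value = TRUE)
  if (length(track_names) == 0) .stage_fail("classify", "no H3K4me1 tracks")
  win <- list()
  for (nm in track_names) {
    parts <- strsplit(sub("^H3K4me1_", "", nm), "_rep")[[1]]
    tr <- rpgc_normalize(read_bedgraph(paths[[nm]],
                                       chrom_lengths = chrom_lengths))
    win[[nm]] <- data.frame(
      enhancer_id = records$peak_id, stage = parts[1],
      replicate = as.integer(parts[2]),
      mean_signal = window_signal(tr, records, flank = thr$flank))
  }
  win <- do.call(rbind, win)
  data.table::fwrite(win, file.path(out, "window_means.tsv"), sep = "\t")
  wide <- data.table::dcast(data.table::as.data.table(win),
                            enhancer_id + replicate ~ stage,
                            value.var = "mean_signal")
  data.table::setnames(wide, c("EpiLC", "EpiSC"), c("epilc", "episc"))
  cls <- classify_groups(as.data.frame(wide),
                         threshold = thr$ratio_threshold,
                         min_replicates = thr$min_replicates,
                         pseudocount = thr$pseudocount)
  data.table::fwrite(cls, file.path(out, "group_classification.tsv"),
                     sep = "\t")
  note("classify", sprintf("Group I: %d, Group II: %d",
                           sum(cls$group == "I"), sum(cls$group == "II")))
  first_rep <- as.data.frame(wide[wide$replicate == min(wide$replicate), ])
  g1 <- cls$enhancer_id[cls$group == "I"]
  if (length(g1) >= 10) {
    first_rep <- first_rep[first_rep$enhancer_id %in% g1, , drop = FALSE]
  }
  eff <- paired_effect_size(first_rep$episc, first_rep$epilc,
                            n_boot = thr$n_boot, seed = config$seed)
  eff_df <- data.frame(mark = "H3K4me1", comparison = "EpiLC_vs_EpiSC",
                       z = eff$z, n = eff$n, r = eff$r,
                       ci_low = eff$ci[1], ci_high = eff$ci[2])
  data.table::fwrite(eff_df, file.path(out, "effect_sizes.tsv"), sep = "\t")
  note("effects", sprintf("r = %.3f [%.3f, %.3f]", eff$r, eff$ci[1],
                          eff$ci[2]))

  # --- methylome heterogeneity --------------------------------------------
  mm <- read_meth_calls(paths$meth_calls, paths$meth_cell_meta)
  calls <- filter_cpg_sites(mm$calls, min_cov = thr$min_cov,
                            max_cov = thr$max_cov)
  regions <- records[, c("chrom", "start", "end")]
  if (nrow(regions) == 0) .stage_fail("heterogeneity", "empty enhancer set")
  keep <- filter_cells_by_region_coverage(calls, regions,
                                          min_sites = thr$min_sites)
  if (length(keep) < 2) .stage_fail("heterogeneity",
                                    "fewer than 2 cells pass site coverage")
  dis <- suppressMessages(
    pairwise_dissimilarity(calls[calls$cell_id %in% keep], regions,
                           cells = keep))
  stages <- stats::setNames(mm$cell_meta$stage, mm$cell_meta$cell_id)
  het <- stage_heterogeneity(dis, stages)
  data.table::fwrite(het, file.path(out, "stage_heterogeneity.tsv"),
                     sep = "\t")
  note("heterogeneity",
       paste(sprintf("%s=%.2f%%", het$stage, het$mean_dissimilarity),
             collapse = " "))

  manifest <- list(
    version = as.character(utils::packageVersion("germcomp")),
    seed = config$seed,
    thresholds = thr,
    inputs = paths,
    outputs = list(
      gene_set = file.path(out, "pgclc_gene_set.tsv"),
      gated_cells = file.path(out, "gated_cells.txt"),
      noise = file.path(out, "transcriptional_noise.tsv"),
      catalog = file.path(out, "enhancer_catalog.tsv"),
      window_means = file.path(out, "window_means.tsv"),
      classification = file.path(out, "group_classification.tsv"),
      effect_sizes = file.path(out, "effect_sizes.tsv"),
      heterogeneity = file.path(out, "stage_heterogeneity.tsv")
    ),
    log = log_lines
  )
  for (pth in unlist(manifest$outputs)) {
    if (!file.exists(pth) || file.size(pth) == 0) {
      .stage_fail("manifest", paste("declared output missing or empty:", pth))
    }
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Validate pipeline input files without running stages
#'
#' Schema checks on the declared inputs: BED coordinate sanity (start <
#' end, non-negative), BEDPE anchor validity, UMI matrix integrality and
#' non-negativity, methylation calls with meth_count <= total_count. Every
#' violation is reported with file and line; nothing is thrown.
#'
#' @param paths named list of input paths (subset of the names written by
#'   [simulate_dataset()]).
#' @return data.frame report: file, line, problem (zero rows when clean).
#' @export
validate_inputs <- function(paths) {
  bad <- list()
  flag <- function(file, line, problem) {
    bad[[length(bad) + 1L]] <<- data.frame(
      file = file, line = line, problem = problem, stringsAsFactors = FALSE)
  }
  check_iv <- function(df, file, off = 0L) {
    viol <- which(df$start < 0 | df$start >= df$end)
    for (i in viol) flag(file, i + off, "interval with start >= end or start < 0")
  }
  if (!is.null(paths$peaks) && file.exists(paths$peaks)) {
    check_iv(read_bed(paths$peaks), paths$peaks)
  }
  if (!is.null(paths$interactions) && file.exists(paths$interactions)) {
    bp <- read_bedpe(paths$interactions)
    a1 <- data.frame(start = bp$start1, end = bp$end1)
    a2 <- data.frame(start = bp$start2, end = bp$end2)
    check_iv(a1, paths$interactions)
    check_iv(a2, paths$interactions)
  }
  if (!is.null(paths$umi_counts) && file.exists(paths$umi_counts)) {
    dt <- data.table::fread(paths$umi_counts, sep = "\t")
    mat <- as.matrix(dt[, -1, with = FALSE])
    badrow <- which(apply(mat, 1, function(r)
      any(r < 0 | r != floor(r))))
    for (i in badrow) flag(paths$umi_counts, i + 1L,
                           "non-integer or negative count")
  }
  if (!is.null(paths$meth_calls) && file.exists(paths$meth_calls)) {
    mc <- data.table::fread(paths$meth_calls, sep = "\t")
    viol <- which(mc$meth_count > mc$total_count | mc$meth_count < 0)
    for (i in viol) flag(paths$meth_calls, i + 1L,
                         "meth_count > total_count or negative")
  }
  if (length(bad) == 0) {
    return(data.frame(file = character(0), line = integer(0),
                      problem = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, bad)
}
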