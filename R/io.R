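# Plain-text readers/writers for the standard formats the pipeline consumes.
# All interval coordinates are BED convention: 0-based, half-open.

#' Write intervals as BED
#' @param df data.frame with chrom, start, end and optional further columns.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file (first three columns mandatory)
#' @param path BED path.
#' @param extra_names names for columns beyond chrom/start/end, if any.
#' @export
read_bed <- function(path, extra_names = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  nm <- c("chrom", "start", "end")
  if (ncol(dt) > 3) {
    more <- extra_names %||% paste0("V", seq_len(ncol(dt) - 3))
    nm <- c(nm, more[seq_len(ncol(dt) - 3)])
  }
  data.table::setnames(dt, nm)
  as.data.frame(dt)
}

#' Write an anchor-pair table as BEDPE
#' @param pairs data.frame with chrom1, start1, end1, chrom2, start2, end2
#'   and optional name/label columns.
#' @param path output path.
#' @export
write_bedpe <- function(pairs, path) {
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  stopifnot(all(need %in% names(pairs)))
  data.table::fwrite(pairs, path, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE file
#' @param path BEDPE path.
#' @export
read_bedpe <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  nm <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (ncol(dt) >= 7) nm <- c(nm, "name")
  if (ncol(dt) >= 8) nm <- c(nm, "label")
  data.table::setnames(dt, seq_along(nm), nm)
  as.data.frame(dt)
}

#' Write a signal track as bedGraph
#' @param track a [signal_track()].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  bs <- track$bin_size
  rows <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    n <- length(v)
    starts <- (seq_len(n) - 1L) * bs
    ends <- pmin(starts + bs, track$chrom_lengths[[ch]])
    data.table::data.table(chrom = ch, start = starts, end = ends,
                           value = v)
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                     quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a fixed-bin bedGraph into a signal track
#'
#' Expects constant-width bins covering each chromosome (the format this
#' package writes); bin width is inferred from the first row.
#'
#' @param path bedGraph path.
#' @param chrom_lengths named chromosome lengths; inferred from the maximal
#'   end per chromosome when omitted.
#' @param ... labels passed to [signal_track()] (mark, stage, replicate,
#'   normalization).
#' @export
read_bedgraph <- function(path, chrom_lengths = NULL, ...) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  bs <- dt$end[1] - dt$start[1]
  if (is.null(chrom_lengths)) {
    agg <- dt[, list(len = max(end)), by = chrom]
    chrom_lengths <- stats::setNames(agg$len, agg$chrom)
  }
  values <- lapply(names(chrom_lengths), function(ch) {
    sub <- dt[dt$chrom == ch]
    n_bins <- as.integer(ceiling(chrom_lengths[[ch]] / bs))
    v <- numeric(n_bins)
    v[sub$start %/% bs + 1L] <- sub$value
    v
  })
  names(values) <- names(chrom_lengths)
  signal_track(values, bin_size = bs, chrom_lengths = chrom_lengths, ...)
}

#' Read a UMI count matrix with cell metadata
#' @param counts_path dense TSV, first column `gene`, one column per cell.
#' @param meta_path cell metadata TSV with at least cell_id and stage.
#' @return an object of class `umi_counts`.
#' @export
read_umi_matrix <- function(counts_path, meta_path) {
  dt <- data.table::fread(counts_path, sep = "\t")
  genes <- dt[[1]]
  counts <- as.matrix(dt[, -1, with = FALSE])
  rownames(counts) <- genes
  storage.mode(counts) <- "integer"
  meta <- as.data.frame(data.table::fread(meta_path, sep = "\t"))
  structure(list(counts = counts, cell_meta = meta, marker_sets = NULL),
            class = "umi_counts")
}

#' Read per-cell CpG methylation calls
#' @param calls_path long TSV: cell_id, chrom, pos, meth_count, total_count.
#' @param meta_path cell metadata TSV (cell_id, stage).
#' @export
read_meth_calls <- function(calls_path, meta_path) {
  calls <- data.table::fread(calls_path, sep = "\t")
  need <- c("cell_id", "chrom", "pos", "meth_count", "total_count")
  stopifnot(all(need %in% names(calls)))
  meta <- as.data.frame(data.table::fread(meta_path, sep = "\t"))
  list(calls = calls, cell_meta = meta)
}
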