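#' Write a genome to FASTA
#' @param genome Named `DNAStringSet`.
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA file.
#' @return Named `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write gene models as GFF3
#'
#' Coordinates are converted from the in-memory 1-based closed `GRanges`
#' representation to GFF3's 1-based closed convention (identical), with
#' `type = "gene"` and `ID = gene_id`.
#' @param genes `GRanges` with `gene_id`.
#' @param path Output file.
#' @export
write_genes_gff3 <- function(genes, path) {
  g <- genes
  g$ID <- g$gene_id
  g$type <- "gene"
  g$source <- "prc2peaks"
  rtracklayer::export(g, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3 (or any rtracklayer-supported annotation)
#' @param path GFF3 file.
#' @return `GRanges` with `gene_id`.
#' @export
read_genes_gff3 <- function(path) {
  g <- rtracklayer::import(path)
  g <- g[g$type %in% "gene" | is.na(g$type)]
  id <- if (!is.null(g$ID)) as.character(g$ID) else as.character(g$Name)
  mcols(g) <- NULL
  g$gene_id <- id
  g
}

#' Write gene models as single-block BED12
#' @param genes `GRanges` with `gene_id`.
#' @param path Output file.
#' @export
write_genes_bed12 <- function(genes, path) {
  dt <- data.table(
    chrom = as.character(seqnames(genes)),
    start = start(genes) - 1L, end = end(genes),
    name = genes$gene_id, score = 0L,
    strand = as.character(strand(genes)),
    thickStart = start(genes) - 1L, thickEnd = end(genes),
    itemRgb = "0,0,0", blockCount = 1L,
    blockSizes = width(genes), blockStarts = 0L)
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write read 5' positions as 6-column BED
#'
#' Each record covers the single 5' base (`end = start + 1` in BED's
#' 0-based half-open coordinates), `score = 0`, strand kept.
#' @param reads `GRanges` of width-1 positions with strand.
#' @param path Output file.
#' @export
write_reads_bed <- function(reads, path) {
  dt <- data.table(
    chrom = as.character(seqnames(reads)),
    start = start(reads) - 1L, end = start(reads),
    name = sprintf("read%d", seq_along(reads)), score = 0L,
    strand = as.character(strand(reads)))
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read read 5' positions from 6-column BED
#' @param path BED file (chrom, start, end, name, score, strand).
#' @param chrom_lengths Optional named vector to set seqlengths and
#'   validate bounds.
#' @return `GRanges` of width-1 5' positions.
#' @export
read_reads_bed <- function(path, chrom_lengths = NULL) {
  dt <- fread(path, header = FALSE)
  gr <- GRanges(dt$V1, IRanges(start = dt$V2 + 1L, width = 1L),
                strand = if (ncol(dt) >= 6L) dt$V6 else "*")
  if (!is.null(chrom_lengths)) {
    seqlengths(gr) <- chrom_lengths[seqlevels(gr)]
    check_reads_in_bounds(gr, chrom_lengths)
  }
  gr
}

#' Write a truth-region table as TSV
#'
#' Columns: region_id, chrom, start, end (0-based half-open), gene_id,
#' mark, fold, coloc_expected.
#' @param truth `GRanges` from [simulate_truth_regions()].
#' @param path Output file.
#' @export
write_truth_tsv <- function(truth, path) {
  dt <- data.table(
    region_id = truth$region_id,
    chrom = as.character(seqnames(truth)),
    start = start(truth) - 1L, end = end(truth),
    gene_id = truth$gene_id, mark = truth$mark, fold = truth$fold,
    coloc_expected = truth$coloc_expected)
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a truth-region table written by [write_truth_tsv()]
#' @param path TSV file.
#' @return `GRanges` with the truth metadata columns.
#' @export
read_truth_tsv <- function(path) {
  dt <- fread(path)
  gr <- GRanges(dt$chrom, IRanges(start = dt$start + 1L, end = dt$end))
  gr$region_id <- dt$region_id
  gr$gene_id <- dt$gene_id
  gr$mark <- dt$mark
  gr$fold <- dt$fold
  gr$coloc_expected <- dt$coloc_expected
  gr
}

#' Load a differential-expression gene list
#'
#' Expects a TSV with columns `gene_id`, `log2fc` and optionally
#' `direction`. The fold-change screen keeps genes de-regulated more than
#' `fold_cutoff`-fold in either direction (`|log2fc| >= log2(fold_cutoff)`);
#' statistical confidence filtering is assumed done upstream by the caller
#' that produced the list.
#'
#' @param path TSV file.
#' @param fold_cutoff Minimum fold de-regulation (default 2).
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return Character vector of gene ids passing the filter.
#' @export
read_expression_tsv <- function(path, fold_cutoff = 2,
                                direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  dt <- fread(path)
  if (!all(c("gene_id", "log2fc") %in% names(dt)))
    stop("expression TSV needs columns gene_id and log2fc")
  keep <- abs(dt$log2fc) >= log2(fold_cutoff)
  if (direction == "up") keep <- keep & dt$log2fc > 0
  if (direction == "down") keep <- keep & dt$log2fc < 0
  unique(dt$gene_id[keep])
}

#' Write scored peaks as BED6+
#'
#' Columns: chrom, start, end (0-based half-open), name, score
#' (`-log10(q)` capped at 1000), strand ".", then k_treat, k_control,
#' max_log2R, p, q.
#' @param peaks `GRanges` from [call_peaks()].
#' @param path Output file.
#' @export
write_peaks_bed <- function(peaks, path) {
  q <- peaks$q
  score <- ifelse(q <= 0, 1000, pmin(1000, -log10(q)))
  dt <- data.table(
    chrom = as.character(seqnames(peaks)),
    start = start(peaks) - 1L, end = end(peaks),
    name = sprintf("peak%d", seq_along(peaks)),
    score = round(score, 2), strand = ".",
    k_treat = peaks$k_treat, k_control = peaks$k_control,
    max_log2R = signif(peaks$max_log2R, 6),
    p = format(peaks$p, digits = 6), q = format(q, digits = 6))
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read intervals from a BED file into GRanges
#' @param path BED file with at least chrom, start, end.
#' @return `GRanges` (1-based closed in memory).
#' @export
read_bed_intervals <- function(path) {
  dt <- fread(path, header = FALSE)
  str <- if (ncol(dt) >= 6L) sub("^\\.$", "*", dt$V6) else "*"
  gr <- GRanges(dt$V1, IRanges(start = dt$V2 + 1L, end = dt$V3),
                strand = str)
  if (ncol(dt) >= 4L) gr$name <- dt$V4
  gr
}

#' Write a window track as bedGraph
#' @param track A `window_track` (see [window_density()]).
#' @param path Output file.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, c("window_track", "ratio_track")))
  w <- track$window_width
  parts <- lapply(names(track$S), function(ch) {
    s <- track$S[[ch]]
    n <- length(s)
    data.table(chrom = ch, start = (seq_len(n) - 1L) * w,
               end = pmin(seq_len(n) * w, track$chrom_lengths[[ch]]),
               value = s)
  })
  fwrite(data.table::rbindlist(parts), path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a metagene profile as TSV
#' @param profile A `metagene_profile` (see [metagene_signal()]).
#' @param path Output file.
#' @export
write_profile_tsv <- function(profile, path) {
  dt <- data.table(bin_label = profile_bin_labels(profile),
                   mean_value = c(profile$upstream, profile$body,
                                  profile$downstream),
                   n_genes = c(profile$n_upstream, profile$n_body,
                               profile$n_downstream))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

profile_bin_labels <- function(profile) {
  c(sprintf("up%02d", seq_along(profile$upstream)),
    sprintf("body%02d", seq_along(profile$body)),
    sprintf("down%02d", seq_along(profile$downstream)))
}

#' Write motif hits as BED6
#' @param hits `GRanges` from [scan_motif()].
#' @param path Output file.
#' @export
write_hits_bed <- function(hits, path) {
  dt <- data.table(
    chrom = as.character(seqnames(hits)),
    start = start(hits) - 1L, end = end(hits),
    name = if (!is.null(hits$pattern)) hits$pattern else ".",
    score = 0L, strand = as.character(strand(hits)))
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
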