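# Fixture builders shared across test files. All coordinates are the
# in-memory GRanges convention (1-based closed); BED-convention values in
# test expectations are converted at the call site.

library(GenomicRanges)

# Regularly spaced gene models on one or more chromosomes.
make_genes <- function(n, gene_len = 2000L, spacing = 3000L,
                       chrom_len = NULL, chroms = "chr1",
                       strands = NULL, offset = 2000L) {
  per <- ceiling(n / length(chroms))
  starts <- offset + (seq_len(per) - 1L) * (gene_len + spacing)
  if (is.null(chrom_len)) chrom_len <- max(starts) + gene_len + offset
  gr <- GRanges(rep(chroms, each = per)[seq_len(n)],
                IRanges(start = rep(starts, length(chroms))[seq_len(n)],
                        width = gene_len),
                strand = if (is.null(strands))
                  rep(c("+", "-"), length.out = n) else strands)
  GenomeInfoDb::seqlevels(gr) <- chroms
  GenomeInfoDb::seqlengths(gr) <- rep(chrom_len, length(chroms))
  gr$gene_id <- sprintf("g%03d", seq_len(n))
  gr
}

# A window_track built directly from a per-window value vector.
make_track <- function(S, window_width = 10L, chrom = "chr1",
                       chrom_len = length(S) * window_width,
                       normalized = TRUE, library_size = 1000L) {
  stopifnot(length(S) == ceiling(chrom_len / window_width))
  structure(list(S = stats::setNames(list(as.numeric(S)), chrom),
                 window_width = as.integer(window_width),
                 chrom_lengths = stats::setNames(chrom_len, chrom),
                 library_size = library_size,
                 scale = 1e6 / library_size, normalized = normalized),
            class = "window_track")
}

# Width-1 stranded read positions.
make_reads <- function(pos, strand, chrom = "chr1", chrom_len = 1e5) {
  gr <- GRanges(chrom, IRanges(start = pos, width = 1L), strand = strand)
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(chrom_len, chrom)
  gr
}

# Random fragments for oracle comparisons.
random_fragments <- function(n, chrom_len, max_len = 250L,
                             chrom = "chr1") {
  s <- sample.int(chrom_len, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  gr <- GRanges(chrom, IRanges(start = s,
                               end = pmin(s + len - 1L, chrom_len)))
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(chrom_len, chrom)
  gr
}

# Small ready-made simulation used by several files.
small_sim <- function(seed = 1L, with_sequence = TRUE, ...) {
  cfg <- sim_config(seed = seed, n_chrom = 1L, chrom_length = 2e5,
                    n_genes = 20L, gene_length_range = c(2000L, 4000L),
                    n_truth_regions = 6L,
                    truth_length_range = c(1000L, 2000L),
                    reads_treatment = 2e4, reads_input = 2e4, ...)
  sim <- simulate_genome(cfg, with_sequence = with_sequence)
  truth <- simulate_truth_regions(cfg, sim$genes)
  list(cfg = cfg, genome = sim$genome, genes = sim$genes,
       chrom_lengths = sim$chrom_lengths, truth = truth)
}
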