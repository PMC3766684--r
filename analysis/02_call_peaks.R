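#!/usr/bin/env Rscript
# Call enrichment peaks for both marks against the shared input library:
# 10 bp window densities, log2 treatment/input ratio, 3-fold threshold,
# 200 bp merging, exact binomial test, BH q-values, q <= 1e-10.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(prc2peaks)
})

indir <- "results/sim"
outdir <- "results/peaks"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

genome <- read_genome_fasta(file.path(indir, "genome.fa"))
clens <- chrom_lengths_of(genome)
input <- read_reads_bed(file.path(indir, "reads_input.bed"), clens)
truth <- read_truth_tsv(file.path(indir, "truth_regions.tsv"))

for (mark in c("A", "B")) {
  L <- if (mark == "A") 200L else 150L   # protein vs histone fragment size
  treat <- read_reads_bed(
    file.path(indir, sprintf("reads_mark%s_treatment.bed", mark)), clens)
  cfg <- peak_call_config(L = L)
  peaks <- call_peaks(treat, input, clens, cfg)
  tm <- truth[truth$mark == mark]
  rec <- truth_recovery(peaks, tm)
  cat(sprintf(
    "mark %s (L = %d): %d peaks at q <= %g; recall %.1f%%, precision %.1f%%\n",
    mark, L, length(peaks), cfg$q_cutoff, 100 * rec$recall,
    100 * rec$precision))
  write_peaks_bed(peaks, file.path(outdir, sprintf("peaks_mark%s.bed", mark)))

  # browser tracks of the normalized treatment density
  frag <- extend_reads(treat, L, clens)
  write_bedgraph(window_density(frag, clens),
                 file.path(outdir, sprintf("density_mark%s.bedgraph", mark)))

  h <- peak_size_histogram(peaks, bin_width = 200)
  data.table::fwrite(h, file.path(outdir,
                                  sprintf("peak_sizes_mark%s.tsv", mark)),
                     sep = "\t")
  cat("  size distribution: median", stats::median(width(peaks)),
      "bp, largest", max(width(peaks)), "bp\n")
}
cat("peak BEDs, density tracks and size histograms written to ",
    outdir, "\n", sep = "")
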