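#!/usr/bin/env Rscript
# Motif work on the called peaks: extract peak sequences (the input an
# external de-novo discovery tool would take), scan the genome for the
# GAGA-like consensus on both strands, check recovery of planted sites,
# and profile hit positions relative to gene bodies.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(prc2peaks)
})

outdir <- "results/motifs"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

genome <- read_genome_fasta("results/sim/genome.fa")
genes <- read_genes_gff3("results/sim/genes.gff3")
pa <- read_bed_intervals("results/peaks/peaks_markA.bed")
planted <- read_bed_intervals("results/sim/motif_truth.bed")

seqs <- extract_peak_sequences(pa, genome)
Biostrings::writeXStringSet(seqs, file.path(outdir, "peak_sequences.fa"))
cat("extracted", length(seqs), "peak sequences (median",
    stats::median(Biostrings::width(seqs)), "bp)\n")

hits <- scan_motif(genome, "GAGAG", both_strands = TRUE)
write_hits_bed(hits, file.path(outdir, "gagag_hits.bed"))
key <- paste(seqnames(hits), start(hits), strand(hits))
pkey <- paste(seqnames(planted), start(planted), strand(planted))
cat(sprintf("GAGAG hits genome-wide: %d; planted sites recovered: %.0f%%\n",
            length(hits), 100 * mean(pkey %in% key)))

in_peaks <- sum(countOverlaps(hits, pa) > 0)
cat(sprintf("hits inside mark-A peaks: %d (%.1f-fold the density expected %s\n",
            in_peaks,
            (in_peaks / sum(width(pa))) /
              ((length(hits) - in_peaks) /
                 (sum(chrom_lengths_of(genome)) - sum(width(pa)))),
            "from the rest of the genome)"))

prof <- motif_positional_distribution(hits, genes, flank_bp = 1000,
                                      n_body_bins = 40, n_flank_bins = 20)
write_profile_tsv(prof, file.path(outdir, "gagag_metagene.tsv"))
cat("hit BED, peak FASTA and positional profile written to ",
    outdir, "\n", sep = "")
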