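#!/usr/bin/env Rscript
# Build the synthetic two-mark ChIP-seq study: a genome with gene models,
# fold-10 enrichment domains for a protein mark (A, FIE-like, L = 200)
# and a histone mark (B, H3K27me3-like, L = 150) that co-locate with
# probability 0.8, GAGA-like motifs planted in target gene bodies, and
# treatment/input read libraries. Everything downstream reads the files
# written here.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(prc2peaks)
})

outdir <- "results/sim"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 20260101, n_chrom = 2, chrom_length = 5e5,
                  n_genes = 100, gene_length_range = c(1800, 3500),
                  n_truth_regions = 30, truth_fold = 10, coloc_prob = 0.8,
                  truth_length_range = c(800, 1600),
                  reads_treatment = 2e5, reads_input = 2e5,
                  fragment_length = 200,
                  motif_pattern = "GAGAG", motif_embed_rate = 3)
print(cfg)

sim <- simulate_genome(cfg)
truth <- simulate_truth_regions(cfg, sim$genes)
cat("placed", length(sim$genes), "genes;",
    sum(truth$mark == "A"), "mark-A and", sum(truth$mark == "B"),
    "mark-B domains;", sum(truth$coloc_expected, na.rm = TRUE),
    "B domains co-located by construction\n")

em <- embed_motifs(sim$genome, sim$genes, truth, cfg$motif_pattern,
                   cfg$motif_embed_rate, seed = cfg$seed + 11L)
cat("planted", length(em$sites), "GAGA-like motif instances in",
    length(unique(em$sites$gene_id)), "target genes\n")

# mark B is a histone mark: its fragments are 150 bp
cfg_b <- cfg
cfg_b$fragment_length <- 150L

write_genome_fasta(em$genome, file.path(outdir, "genome.fa"))
write_genes_gff3(sim$genes, file.path(outdir, "genes.gff3"))
write_genes_bed12(sim$genes, file.path(outdir, "genes.bed12"))
write_truth_tsv(truth, file.path(outdir, "truth_regions.tsv"))
write_hits_bed(em$sites, file.path(outdir, "motif_truth.bed"))
write_reads_bed(simulate_reads(cfg, truth, "treatment", mark = "A"),
                file.path(outdir, "reads_markA_treatment.bed"))
write_reads_bed(simulate_reads(cfg_b, truth, "treatment", mark = "B"),
                file.path(outdir, "reads_markB_treatment.bed"))
write_reads_bed(simulate_reads(cfg, truth, "input"),
                file.path(outdir, "reads_input.bed"))
cat("wrote genome, annotation, truth tables and three read libraries to ",
    outdir, "\n", sep = "")
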