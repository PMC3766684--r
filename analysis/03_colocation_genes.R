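#!/usr/bin/env Rscript
# Co-location of the two marks and assignment of peaks to genes: classify
# every peak as co-located or mark-specific (>= 1 bp overlap), map peaks
# to the genes they overlap, and compare the resulting gene sets.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(prc2peaks)
})

outdir <- "results/colocation"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

genes <- read_genes_gff3("results/sim/genes.gff3")
truth <- read_truth_tsv("results/sim/truth_regions.tsv")
pa <- read_bed_intervals("results/peaks/peaks_markA.bed")
pb <- read_bed_intervals("results/peaks/peaks_markB.bed")

co <- categorize_overlap(pa, pb)
print(co)
expected <- mean(truth$coloc_expected[truth$mark == "B"])
cat(sprintf(
  "co-located fraction of mark-B peaks: %.3f (construction: %.3f)\n",
  co$n_b_ab / co$n_b, expected))
jsonlite::write_json(
  list(n_A = co$n_a, n_B = co$n_b, n_AB_from_A = co$n_ab,
       A_only = co$n_a_only, n_AB_from_B = co$n_b_ab,
       B_only = co$n_b_only),
  file.path(outdir, "venn_counts.json"), auto_unbox = TRUE)

ga <- assign_peaks_to_genes(pa, genes)
gb <- assign_peaks_to_genes(pb, genes)
cat(sprintf("mark A peaks map to %d genes, mark B peaks to %d genes\n",
            length(ga$genes), length(gb$genes)))
sets <- compare_gene_sets(ga$genes, gb$genes)
cat(sprintf("%.1f%% of mark-A genes also carry mark B (%d shared)\n",
            sets$percent_a, sets$overlap))

dt <- data.table::data.table(
  gene_id = union(ga$genes, gb$genes))
dt$mark_A <- dt$gene_id %in% ga$genes
dt$mark_B <- dt$gene_id %in% gb$genes
data.table::fwrite(dt, file.path(outdir, "peak_genes.tsv"), sep = "\t")
cat("gene table and Venn counts written to ", outdir, "\n", sep = "")
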