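test_that("genome generation places non-overlapping genes and is deterministic", {
  cfg <- sim_config(seed = 1, n_chrom = 1, chrom_length = 1e5,
                    n_genes = 10, gene_length_range = c(1000, 3000),
                    n_truth_regions = 5)
  sim <- simulate_genome(cfg)
  expect_length(sim$genes, 10)
  expect_true(all(start(sim$genes) >= 1))
  expect_true(all(end(sim$genes) <= 1e5))
  ov <- findOverlaps(sim$genes, ignore.strand = TRUE,
                     drop.self = TRUE)
  expect_length(ov, 0)
  expect_equal(Biostrings::width(sim$genome), 1e5)

  sim2 <- simulate_genome(cfg)
  expect_identical(as.character(sim$genome), as.character(sim2$genome))
  expect_identical(sim$genes, sim2$genes)

  cfg0 <- sim_config(seed = 1, n_chrom = 1, chrom_length = 1e4,
                     n_genes = 0, n_truth_regions = 0)
  sim0 <- simulate_genome(cfg0)
  expect_length(sim0$genes, 0)
  expect_equal(Biostrings::width(sim0$genome), 1e4)
})

test_that("generator outputs survive a write/read round trip byte-identically", {
  cfg <- sim_config(seed = 3, n_chrom = 2, chrom_length = 2e4,
                    n_genes = 6, n_truth_regions = 3,
                    gene_length_range = c(1000, 2000),
                    truth_length_range = c(300, 600),
                    reads_input = 500, reads_treatment = 500)
  sim <- simulate_genome(cfg)
  truth <- simulate_truth_regions(cfg, sim$genes)
  reads <- simulate_reads(cfg, truth, "input")

  d <- withr::local_tempdir()
  fa <- file.path(d, "g.fa"); write_genome_fasta(sim$genome, fa)
  expect_identical(as.character(read_genome_fasta(fa)),
                   as.character(sim$genome))
  gff <- file.path(d, "genes.gff3"); write_genes_gff3(sim$genes, gff)
  back <- read_genes_gff3(gff)
  expect_equal(start(back), start(sim$genes))
  expect_equal(end(back), end(sim$genes))
  expect_equal(back$gene_id, sim$genes$gene_id)
  bed <- file.path(d, "reads.bed"); write_reads_bed(reads, bed)
  rback <- read_reads_bed(bed, chrom_lengths_of(sim$genome))
  expect_equal(start(rback), start(reads))
  expect_equal(as.character(strand(rback)), as.character(strand(reads)))
  tsv <- file.path(d, "truth.tsv"); write_truth_tsv(truth, tsv)
  tback <- read_truth_tsv(tsv)
  expect_equal(start(tback), start(truth))
  expect_equal(tback$mark, truth$mark)
  expect_equal(tback$coloc_expected, truth$coloc_expected)
})

test_that("truth regions sit inside gene bodies with the requested co-location", {
  s <- small_sim(seed = 2, with_sequence = FALSE)
  truth <- s$truth
  a <- truth[truth$mark == "A"]; b <- truth[truth$mark == "B"]
  for (tr in list(a, b)) {
    g <- s$genes[match(tr$gene_id, s$genes$gene_id)]
    expect_true(all(start(tr) >= start(g) & end(tr) <= end(g)))
  }
  expect_true(all(width(truth) > 0))
  # within-mark genes are distinct
  expect_false(any(duplicated(a$gene_id)))
  expect_false(any(duplicated(b$gene_id)))

  cfg1 <- sim_config(seed = 5, n_chrom = 1, chrom_length = 2e5,
                     n_genes = 30, n_truth_regions = 10, coloc_prob = 1,
                     gene_length_range = c(2000, 4000))
  genes <- simulate_genome(cfg1, with_sequence = FALSE)$genes
  t1 <- simulate_truth_regions(cfg1, genes)
  a1 <- t1[t1$mark == "A"]; b1 <- t1[t1$mark == "B"]
  expect_identical(ranges(a1), ranges(b1))
  expect_identical(a1$gene_id, b1$gene_id)
  expect_true(all(b1$coloc_expected))

  cfg0 <- sim_config(seed = 5, n_chrom = 1, chrom_length = 2e5,
                     n_genes = 30, n_truth_regions = 10, coloc_prob = 0,
                     gene_length_range = c(2000, 4000))
  t0 <- simulate_truth_regions(cfg0, genes)
  expect_length(intersect(t0$gene_id[t0$mark == "A"],
                          t0$gene_id[t0$mark == "B"]), 0)
  expect_false(any(t0$coloc_expected[t0$mark == "B"]))

  expect_error(sim_config(n_genes = 5, n_truth_regions = 10),
               "n_truth_regions")
})

test_that("co-located fraction matches the binomial sampling expectation", {
  genes <- make_genes(500, gene_len = 2000L, spacing = 500L)
  fracs <- vapply(1:20, function(seed) {
    cfg <- sim_config(seed = seed, n_chrom = 1,
                      chrom_length = max(end(genes)) + 2000,
                      n_genes = 500, n_truth_regions = 200,
                      coloc_prob = 0.8)
    tr <- simulate_truth_regions(cfg, genes)
    mean(tr$coloc_expected[tr$mark == "B"])
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.8), 0.06)
})

test_that("read sampling conserves counts and concentrates mass in enriched regions", {
  cfg <- sim_config(seed = 4, n_chrom = 2, chrom_length = 1e5,
                    n_genes = 10, n_truth_regions = 5, truth_fold = 10,
                    coloc_prob = 1, gene_length_range = c(2000, 4000),
                    reads_input = 1000, reads_treatment = 5000)
  sim <- simulate_genome(cfg, with_sequence = FALSE)
  # confine truth regions to chr1 genes
  g1 <- sim$genes[seqnames(sim$genes) == "chr1"]
  truth <- simulate_truth_regions(cfg, g1)
  ri <- simulate_reads(cfg, truth, "input")
  expect_length(ri, 1000)
  rt <- simulate_reads(cfg, truth, "treatment")
  expect_length(rt, 5000)
  share <- mean(seqnames(rt) == "chr1")
  expect_gt(share, 0.5)  # length share is 0.5; fold-10 domains add mass
  # determinism
  rt2 <- simulate_reads(cfg, truth, "treatment")
  expect_identical(start(rt), start(rt2))
})

test_that("treatment reads are marginally uniform when fold is 1", {
  cfg <- sim_config(seed = 7, n_chrom = 1, chrom_length = 2e5,
                    n_genes = 20, n_truth_regions = 10, truth_fold = 1,
                    gene_length_range = c(2000, 4000),
                    reads_treatment = 5e4)
  sim <- simulate_genome(cfg, with_sequence = FALSE)
  truth <- simulate_truth_regions(cfg, sim$genes)
  rt <- simulate_reads(cfg, truth, "treatment")
  ks <- suppressWarnings(
    stats::ks.test((start(rt) - 0.5) / 2e5, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("motif embedding is Poisson-calibrated and scanner-recoverable", {
  cfg <- sim_config(seed = 5, n_chrom = 1, chrom_length = 1e6,
                    n_genes = 100, n_truth_regions = 100, coloc_prob = 1,
                    gene_length_range = c(2000, 4000),
                    truth_length_range = c(500, 1500))
  sim <- simulate_genome(cfg)
  truth <- simulate_truth_regions(cfg, sim$genes)

  em0 <- embed_motifs(sim$genome, sim$genes, truth, "GAGAG", 0, seed = 5)
  expect_identical(as.character(em0$genome), as.character(sim$genome))
  expect_length(em0$sites, 0)

  em <- embed_motifs(sim$genome, sim$genes, truth, "GAGAG", 3, seed = 5)
  n_planted <- length(em$sites)
  expect_lt(abs(n_planted - 300), 3 * sqrt(300))

  # every planted site is inside its target gene body
  g <- sim$genes[match(em$sites$gene_id, sim$genes$gene_id)]
  expect_true(all(start(em$sites) >= start(g) &
                    end(em$sites) <= end(g)))

  # full recall by the scanner, with matching strand
  hits <- scan_motif(em$genome, "GAGAG", both_strands = TRUE)
  key <- paste(seqnames(hits), start(hits), strand(hits))
  planted_key <- paste(seqnames(em$sites), start(em$sites),
                       strand(em$sites))
  expect_true(all(planted_key %in% key))
})

test_that("up-regulated gene sampling respects group rates", {
  groups <- list(a = sprintf("a%03d", 1:400), b = sprintf("b%03d", 1:400))
  up <- simulate_up_genes(groups, c(0.3, 0.12), seed = 9)
  fa <- mean(groups$a %in% up)
  fb <- mean(groups$b %in% up)
  expect_lt(abs(fa - 0.3), 3 * sqrt(0.3 * 0.7 / 400))
  expect_lt(abs(fb - 0.12), 3 * sqrt(0.12 * 0.88 / 400))
})
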