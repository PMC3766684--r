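test_that("co-location uses the 1 bp half-open overlap rule", {
  # BED [100,200) and [199,300): 1 bp shared -> co-located
  a <- GRanges("chr1", IRanges(start = 101, end = 200))
  b <- GRanges("chr1", IRanges(start = 200, end = 300))
  res <- categorize_overlap(a, b)
  expect_equal(res$n_ab, 1)
  expect_equal(res$n_b_ab, 1)

  # BED [100,200) and [200,300): adjacent, no shared base
  b2 <- GRanges("chr1", IRanges(start = 201, end = 300))
  res2 <- categorize_overlap(a, b2)
  expect_equal(res2$n_ab, 0)
  expect_equal(res2$n_a_only, 1)
  expect_equal(res2$n_b_only, 1)
})

test_that("co-location counts match the all-pairs oracle and partition the sets", {
  withr::with_seed(2, {
    mk <- function(n) {
      s <- sample.int(50000, n, replace = TRUE)
      GRanges(sample(c("chr1", "chr2"), n, replace = TRUE),
              IRanges(start = s, width = sample.int(800, n, replace = TRUE)))
    }
    a <- mk(500); b <- mk(500)
  })
  res <- categorize_overlap(a, b)
  hit <- oracle_overlap_matrix(start(a), end(a),
                               as.character(seqnames(a)),
                               start(b), end(b),
                               as.character(seqnames(b)))
  expect_equal(res$n_ab, sum(rowSums(hit) > 0))
  expect_equal(res$n_b_ab, sum(colSums(hit) > 0))
  expect_equal(res$n_ab + res$n_a_only, length(a))
  expect_equal(res$n_b_ab + res$n_b_only, length(b))

  # transposition
  tres <- categorize_overlap(b, a)
  expect_equal(tres$n_ab, res$n_b_ab)
  expect_equal(tres$n_b_ab, res$n_ab)
})

test_that("peaks are assigned to every overlapped gene", {
  genes <- make_genes(4, gene_len = 1000L, spacing = 0L, offset = 1001L)
  # inside gene 2 only
  p1 <- GRanges("chr1", IRanges(start = 2100, end = 2200))
  a1 <- assign_peaks_to_genes(p1, genes)
  expect_equal(a1$genes, "g002")
  # spanning genes 2 and 3 (adjacent)
  p2 <- GRanges("chr1", IRanges(start = 2900, end = 3100))
  a2 <- assign_peaks_to_genes(p2, genes)
  expect_setequal(a2$genes, c("g002", "g003"))
  expect_setequal(a2$peak_genes[[1]], c("g002", "g003"))
  # flank widening catches a promoter-proximal peak
  p3 <- GRanges("chr1", IRanges(start = 700, end = 900))
  expect_length(assign_peaks_to_genes(p3, genes)$genes, 0)
  expect_equal(assign_peaks_to_genes(p3, genes, flank = 200)$genes, "g001")
  # unknown chromosome -> warning, unassigned
  p4 <- GRanges("chrX", IRanges(start = 10, end = 20))
  expect_warning(a4 <- assign_peaks_to_genes(p4, genes), "unassigned")
  expect_length(a4$genes, 0)
})

test_that("gene assignment matches the all-pairs oracle on random sets", {
  withr::with_seed(12, {
    s <- sample.int(80000, 300, replace = TRUE)
    peaks <- GRanges("chr1", IRanges(start = s,
                                     width = sample.int(1500, 300,
                                                        replace = TRUE)))
    genes <- make_genes(40, gene_len = 1500L, spacing = 700L)
  })
  res <- assign_peaks_to_genes(peaks, genes)
  hit <- oracle_overlap_matrix(start(peaks), end(peaks),
                               as.character(seqnames(peaks)),
                               start(genes), end(genes),
                               as.character(seqnames(genes)))
  oracle_pairs <- which(hit, arr.ind = TRUE)
  expect_equal(nrow(res$map), nrow(oracle_pairs))
  got <- paste(res$map$peak, res$map$gene_id)
  want <- paste(oracle_pairs[, 1], genes$gene_id[oracle_pairs[, 2]])
  expect_setequal(got, want)
})

test_that("peak size histogram bins lengths by floor division", {
  # BED lengths 150, 250, 399
  pk <- GRanges("chr1", IRanges(start = c(1, 1000, 2000),
                                width = c(150, 250, 399)))
  h <- peak_size_histogram(pk, 200)
  expect_equal(h$count, c(1, 2))
  expect_equal(h$bin_start, c(0, 200))

  expect_equal(nrow(peak_size_histogram(GRanges(), 200)), 0)

  withr::with_seed(14, {
    pk2 <- GRanges("chr1", IRanges(start = sample.int(1e5, 1000),
                                   width = sample.int(3000, 1000,
                                                      replace = TRUE)))
  })
  expect_equal(sum(peak_size_histogram(pk2, 200)$count), 1000)
})

test_that("gene-set comparison performs exact set algebra", {
  res <- compare_gene_sets(c("g1", "g2", "g3", "g4"),
                           c("g1", "g2", "g3", "g5"))
  expect_equal(res$overlap, 3)
  expect_equal(res$percent_a, 75)
  expect_equal(res$b_only, 1)

  same <- compare_gene_sets(letters[1:5], letters[1:5])
  expect_equal(same$percent_a, 100)
  expect_equal(compare_gene_sets(letters[1:3], letters[10:12])$percent_a, 0)
  expect_error(compare_gene_sets(character(0), "g1"), "empty")
})

test_that("up-regulated fractions and their ratio recover simulated rates", {
  expect_equal(upregulated_fraction(c("a", "b", "c", "d"),
                                    c("a", "b", "x")), 0.5)
  expect_equal(upregulated_fraction(c("a", "b"), c("a", "b", "c")), 1)
  expect_error(upregulated_fraction(character(0), "a"), "undefined")

  # co-located-mark genes up-regulated at 0.3 vs 0.12 for single-mark
  groups <- list(ab = sprintf("ab%03d", 1:500),
                 b_only = sprintf("b%03d", 1:500))
  up <- simulate_up_genes(groups, c(0.3, 0.12), seed = 9)
  res <- upregulated_ratio(groups$ab, groups$b_only, up)
  expect_lt(abs(res$fraction1 - 0.3), 3 * sqrt(0.3 * 0.7 / 500))
  expect_lt(abs(res$fraction2 - 0.12), 3 * sqrt(0.12 * 0.88 / 500))
  expect_gt(res$ratio, 1.6)
  expect_lt(res$ratio, 3.9)
})

test_that("hypergeometric enrichment matches the exact tail and applies BH", {
  pop <- sprintf("g%02d", 1:10)
  ann <- list(cat1 = pop[1:5])
  res <- hypergeom_enrichment(pop[1:4], pop, list(cat1 = pop[1:4],
                                                  catA = pop[1:5]))
  # k=4, K=4 category: p = C(4,4)C(6,0)/C(10,4) = 1/210
  expect_equal(res[res$category == "cat1"]$p, 1 / 210, tolerance = 1e-12)
  # k=4 of K=5: p = C(5,4)C(5,0)/C(10,4) + C(5,5).../ ... oracle check
  expect_equal(res[res$category == "catA"]$p,
               oracle_hyper_tail(10, 5, 4, 4), tolerance = 1e-12)

  # k = 0 -> p = 1
  res0 <- hypergeom_enrichment(pop[6:9], pop, list(z = pop[1:2]))
  expect_equal(res0$p, 1)

  # empty category skipped with warning; BH column matches bh_qvalues
  expect_warning(
    res2 <- hypergeom_enrichment(pop[1:4], pop,
                                 list(a = pop[1:5], b = pop[3:8],
                                      empty = character(0))),
    "skipped")
  expect_equal(res2$q, bh_qvalues(res2$p))
  expect_error(hypergeom_enrichment(c("zz"), pop, ann), "subset")
})

test_that("hypergeometric p agrees with brute-force summation on random draws", {
  withr::with_seed(33, {
    for (i in 1:100) {
      N <- sample(5:100, 1)
      K <- sample.int(N, 1)
      n <- sample.int(N, 1)
      pop <- sprintf("g%03d", 1:N)
      study <- sample(pop, n)
      ann <- list(c1 = pop[1:K])
      k <- length(intersect(study, ann$c1))
      res <- hypergeom_enrichment(study, pop, ann)
      expect_equal(res$p, oracle_hyper_tail(N, K, n, k),
                   tolerance = 1e-12)
    }
  })
})

test_that("expression lists are filtered at 2-fold de-regulation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  dt <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5"),
                   log2fc = c(1.5, -2.0, 0.5, 1.0, -0.99))
  write.table(dt, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_setequal(read_expression_tsv(path), c("g1", "g2", "g4"))
  expect_setequal(read_expression_tsv(path, direction = "up"),
                  c("g1", "g4"))
  expect_setequal(read_expression_tsv(path, direction = "down"), "g2")
  expect_setequal(read_expression_tsv(path, fold_cutoff = 4), "g2")
})
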