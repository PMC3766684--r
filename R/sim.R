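#' Simulation configuration for synthetic ChIP-seq experiments
#'
#' Bundles every parameter of the synthetic-data generator: a random genome
#' with non-overlapping gene models, gene-body enrichment domains ("truth
#' regions") for two chromatin marks whose co-location rate is controlled,
#' treatment/input read sets sampled under a uniform background plus
#' fold-weighted enrichment model, and IUPAC motifs embedded in target gene
#' bodies. Identical configurations (including `seed`) produce
#' byte-identical outputs; each generation stage draws from its own
#' deterministic RNG substream so stages are independently reproducible.
#'
#' @param seed Master RNG seed (integer).
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param n_genes Total number of genes across the genome.
#' @param gene_length_range Length-2 vector, min/max gene length in bp.
#' @param n_truth_regions Number of enrichment domains per mark.
#' @param truth_fold Enrichment fold of true domains relative to background
#'   (dimensionless, >= 1; 1 means no enrichment).
#' @param coloc_prob Probability in `[0,1]` that a mark-B domain co-locates
#'   (identical interval, same gene) with a mark-A domain.
#' @param truth_length_range Length-2 vector, min/max domain length in bp
#'   (clipped to the host gene body).
#' @param reads_treatment,reads_input Read counts per sample.
#' @param fragment_length Fragment length L used when sampling treatment
#'   reads so the extended fragment lies within its domain.
#' @param motif_pattern IUPAC consensus to embed in target gene bodies.
#' @param motif_embed_rate Expected embedded motifs per target gene
#'   (Poisson mean).
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_chrom = 1, chrom_length = 1e5, n_genes = 10)
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_length = 5e5,
                       n_genes = 100L,
                       gene_length_range = c(1000L, 3000L),
                       n_truth_regions = 30L,
                       truth_fold = 10,
                       coloc_prob = 0.8,
                       truth_length_range = c(500L, 1500L),
                       reads_treatment = 2e5,
                       reads_input = 2e5,
                       fragment_length = 200L,
                       motif_pattern = "GAGAG",
                       motif_embed_rate = 3) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              n_truth_regions = as.integer(n_truth_regions),
              truth_fold = as.numeric(truth_fold),
              coloc_prob = as.numeric(coloc_prob),
              truth_length_range = as.integer(truth_length_range),
              reads_treatment = as.integer(reads_treatment),
              reads_input = as.integer(reads_input),
              fragment_length = as.integer(fragment_length),
              motif_pattern = toupper(motif_pattern),
              motif_embed_rate = as.numeric(motif_embed_rate))
  if (cfg$n_chrom < 1L || cfg$chrom_length < 1L)
    stop("need at least one chromosome of positive length")
  if (cfg$n_genes < 0L) stop("n_genes must be >= 0")
  if (cfg$n_truth_regions > cfg$n_genes)
    stop("n_truth_regions exceeds n_genes: each domain needs its own gene")
  if (cfg$truth_fold < 1) stop("truth_fold must be >= 1")
  if (cfg$coloc_prob < 0 || cfg$coloc_prob > 1)
    stop("coloc_prob must lie in [0, 1]")
  if (length(cfg$gene_length_range) != 2L ||
      diff(cfg$gene_length_range) < 0L || cfg$gene_length_range[1] < 1L)
    stop("gene_length_range must be an increasing positive pair")
  if (length(cfg$truth_length_range) != 2L ||
      diff(cfg$truth_length_range) < 0L || cfg$truth_length_range[1] < 1L)
    stop("truth_length_range must be an increasing positive pair")
  if (cfg$fragment_length < 1L) stop("fragment_length must be positive")
  if (cfg$motif_embed_rate < 0) stop("motif_embed_rate must be >= 0")
  iupac_check(cfg$motif_pattern)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chrom, "chrom x", x$chrom_length, "bp,",
      x$n_genes, "genes,", x$n_truth_regions, "truth regions (fold",
      x$truth_fold, "), coloc_prob", x$coloc_prob, ", seed", x$seed, "\n")
  invisible(x)
}

#' Generate a random genome and non-overlapping gene models
#'
#' Chromosome sequences are i.i.d. uniform over A/C/G/T. Genes are placed
#' on both strands without overlap by rejection sampling, distributed
#' round-robin across chromosomes; an error is raised if a gene cannot be
#' placed after a bounded number of retries (genome too crowded).
#'
#' @param cfg A [sim_config()].
#' @param with_sequence Generate the nucleotide sequence? Set `FALSE` for
#'   simulations that only need coordinates (read sampling and peak
#'   calling never touch the sequence); `genome` is then `NULL`.
#' @return A list with `genome` (a named `DNAStringSet`, or `NULL`),
#'   `genes` (a `GRanges` with `gene_id` metadata and seqlengths set) and
#'   `chrom_lengths` (named vector).
#' @examples
#' sim <- simulate_genome(sim_config(seed = 1, n_chrom = 1,
#'   chrom_length = 5e4, n_genes = 5))
#' @export
simulate_genome <- function(cfg, with_sequence = TRUE) {
  stopifnot(is(cfg, "sim_config"))
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  genome <- NULL
  if (with_sequence) {
    genome <- withr::with_seed(stage_seed(cfg$seed, "genome"), {
      seqs <- vapply(chroms, function(ch) {
        paste(sample(c("A", "C", "G", "T"), cfg$chrom_length,
                     replace = TRUE), collapse = "")
      }, character(1))
      Biostrings::DNAStringSet(seqs)
    })
    names(genome) <- chroms
  }

  genes <- withr::with_seed(stage_seed(cfg$seed, "genes"), {
    place_genes(cfg, chroms)
  })
  clens <- stats::setNames(rep(cfg$chrom_length, cfg$n_chrom), chroms)
  genes <- set_genome_info(genes, clens)
  list(genome = genome, genes = genes, chrom_lengths = clens)
}

# Rejection-sampling gene placement; bounded retries per gene.
place_genes <- function(cfg, chroms, max_tries = 2000L) {
  if (cfg$n_genes == 0L) {
    return(GRanges(seqnames = character(0), IRanges(), strand = character(0),
                   gene_id = character(0)))
  }
  chrom_of <- rep(chroms, length.out = cfg$n_genes)
  placed <- vector("list", cfg$n_genes)
  occupied <- lapply(chroms, function(x) IRanges())
  names(occupied) <- chroms
  for (i in seq_len(cfg$n_genes)) {
    ch <- chrom_of[i]
    len <- sample(cfg$gene_length_range[1]:cfg$gene_length_range[2], 1L)
    if (len > cfg$chrom_length)
      stop("gene length exceeds chromosome length")
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(cfg$chrom_length - len + 1L, 1L)  # 1-based start
      cand <- IRanges(start = s, width = len)
      if (countOverlaps(cand, occupied[[ch]]) == 0L) {
        occupied[[ch]] <- c(occupied[[ch]], cand)
        placed[[i]] <- list(chrom = ch, start = s, width = len,
                            strand = sample(c("+", "-"), 1L))
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place gene ", i, " without overlap after ",
           max_tries, " tries; reduce n_genes or gene lengths")
    }
  }
  gr <- GRanges(
    seqnames = vapply(placed, `[[`, character(1), "chrom"),
    ranges = IRanges(start = vapply(placed, `[[`, numeric(1), "start"),
                     width = vapply(placed, `[[`, numeric(1), "width")),
    strand = vapply(placed, `[[`, character(1), "strand"))
  gr$gene_id <- sprintf("gene%04d", seq_len(cfg$n_genes))
  sort(gr, ignore.strand = TRUE)
}

#' Generate truth enrichment domains for marks A and B
#'
#' Mark-A domains model direct protein binding regions; mark-B domains
#' model a second chromatin mark. Each domain lies within a distinct gene
#' body (one domain per gene per mark). Each mark-B domain independently
#' co-locates with its paired mark-A domain — taking the identical interval
#' in the same gene — with probability `cfg$coloc_prob`; otherwise it is
#' placed in a gene not used by mark A, so non-co-located domains are
#' gene-disjoint from mark A.
#'
#' @param cfg A [sim_config()].
#' @param genes `GRanges` of gene models with `gene_id`.
#' @return A `GRanges` of truth regions with metadata `region_id`,
#'   `gene_id`, `mark` ("A"/"B"), `fold`, and for mark B `coloc_expected`
#'   (logical; `NA` for mark A).
#' @export
simulate_truth_regions <- function(cfg, genes) {
  stopifnot(is(cfg, "sim_config"))
  n <- cfg$n_truth_regions
  if (n == 0L) {
    out <- GRanges()
    out <- set_genome_info(out,
      stats::setNames(rep(cfg$chrom_length, cfg$n_chrom),
                      paste0("chr", seq_len(cfg$n_chrom))))
    return(out)
  }
  if (length(genes) == 0L) stop("truth regions require genes")
  withr::with_seed(stage_seed(cfg$seed, "truth"), {
    idx_a <- sample.int(length(genes), n)
    coloc <- runif(n) < cfg$coloc_prob
    pool_b <- setdiff(seq_along(genes), idx_a)
    if (sum(!coloc) > length(pool_b)) {
      stop("not enough genes to place non-co-located mark-B domains; ",
           "increase n_genes")
    }
    idx_b <- idx_a
    idx_b[!coloc] <- sample(pool_b, sum(!coloc))

    region_in_gene <- function(g) {
      len <- sample(cfg$truth_length_range[1]:cfg$truth_length_range[2], 1L)
      len <- min(len, width(g))
      s <- start(g) + sample.int(width(g) - len + 1L, 1L) - 1L
      IRanges(start = s, width = len)
    }
    ra <- do.call(c, lapply(seq_len(n),
                            function(i) region_in_gene(genes[idx_a[i]])))
    a <- GRanges(seqnames(genes)[idx_a], ra, strand = "*")
    a$region_id <- sprintf("A%03d", seq_len(n))
    a$gene_id <- genes$gene_id[idx_a]
    a$mark <- "A"
    a$fold <- cfg$truth_fold
    a$coloc_expected <- NA

    b <- GRanges(seqnames(genes)[idx_b],
                 do.call(c, lapply(seq_len(n), function(i) {
                   if (coloc[i]) ra[i] else region_in_gene(genes[idx_b[i]])
                 })), strand = "*")
    b$region_id <- sprintf("B%03d", seq_len(n))
    b$gene_id <- genes$gene_id[idx_b]
    b$mark <- "B"
    b$fold <- cfg$truth_fold
    b$coloc_expected <- coloc

    out <- c(a, b)
    out <- set_genome_info(out, seqlengths(genes))
    out
  })
}

#' Sample read 5' positions for a treatment or input library
#'
#' Input reads are uniform over the genome with random strand — the
#' micrococcal-nuclease-digested input control has no positional structure.
#' Treatment reads are a mixture of the same uniform background and reads
#' whose extended fragment of length `cfg$fragment_length` lies within a
#' truth region; each region receives extra sampling weight
#' `(fold - 1) * width`, so its expected read density is `fold` times
#' background. With `truth_fold = 1` the treatment marginal is exactly
#' uniform. Emitted read counts equal the requested counts exactly.
#'
#' @param cfg A [sim_config()].
#' @param truth `GRanges` of truth regions (see
#'   [simulate_truth_regions()]); only rows of `mark` are used.
#' @param sample_type `"treatment"` or `"input"`.
#' @param mark Which mark's domains drive treatment enrichment.
#' @return `GRanges` of width-1 read 5' positions with strand, seqlengths
#'   set.
#' @export
simulate_reads <- function(cfg, truth, sample_type = c("treatment", "input"),
                           mark = "A") {
  stopifnot(is(cfg, "sim_config"))
  sample_type <- match.arg(sample_type)
  n_reads <- if (sample_type == "treatment") cfg$reads_treatment else
    cfg$reads_input
  if (n_reads <= 0L) stop("read count must be positive")
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  clens <- stats::setNames(rep(cfg$chrom_length, cfg$n_chrom), chroms)
  G <- sum(as.numeric(clens))
  L <- cfg$fragment_length

  regions <- if (sample_type == "treatment" && length(truth) > 0L) {
    truth[truth$mark == mark]
  } else {
    GRanges()
  }
  if (length(regions) > 0L && any(width(regions) < L)) {
    warning(sum(width(regions) < L),
            " truth region(s) shorter than fragment length; ",
            "fragments clipped to the region/chromosome")
  }

  seed <- stage_seed(cfg$seed,
                     if (sample_type == "treatment") "reads_treatment"
                     else "reads_input")
  # distinct substream per mark so two treatment libraries are independent
  seed <- seed + 29L * (match(mark, LETTERS) - 1L)
  withr::with_seed(seed, {
    extra_w <- if (length(regions) > 0L)
      (regions$fold - 1) * width(regions) else numeric(0)
    total_w <- G + sum(extra_w)
    # component 0 = uniform background, 1..R = regions
    comp <- sample.int(length(extra_w) + 1L, n_reads, replace = TRUE,
                       prob = c(G, extra_w) / total_w) - 1L
    strand_all <- sample(c("+", "-"), n_reads, replace = TRUE)
    pos <- integer(n_reads)
    chrom <- character(n_reads)

    bg <- comp == 0L
    if (any(bg)) {
      chrom[bg] <- sample(chroms, sum(bg), replace = TRUE,
                          prob = clens / G)
      pos[bg] <- floor(runif(sum(bg)) * clens[chrom[bg]]) + 1L
    }
    for (r in seq_along(extra_w)) {
      sel <- comp == r
      if (!any(sel)) next
      g <- regions[r]
      chrom[sel] <- as.character(seqnames(g))
      plus <- strand_all[sel] == "+"
      # + strand: fragment [p, p+L) inside region => p in [start, end-L+1]
      lo_p <- start(g); hi_p <- max(start(g), end(g) - L + 1L)
      # - strand: fragment [p-L+1, p+1) inside => p in [start+L-1, end]
      lo_m <- min(end(g), start(g) + L - 1L); hi_m <- end(g)
      p <- integer(sum(sel))
      p[plus] <- lo_p + floor(runif(sum(plus)) * (hi_p - lo_p + 1L))
      p[!plus] <- lo_m + floor(runif(sum(!plus)) * (hi_m - lo_m + 1L))
      pos[sel] <- p
    }
    gr <- GRanges(chrom, IRanges(start = pos, width = 1L),
                  strand = strand_all)
    gr <- set_genome_info(gr, clens)
    sort(gr, ignore.strand = TRUE)
  })
}

#' Embed concrete motif instances in truth-region gene bodies
#'
#' Plants `Poisson(rate)` instances of the IUPAC pattern per target gene
#' (the genes carrying truth regions), at uniformly random non-overlapping
#' positions fully inside the gene body, on a random strand (minus-strand
#' sites are written as the reverse complement). Ambiguity codes are
#' resolved uniformly at random per planted site. Every planted site is
#' recorded so scanner recall can be computed exactly.
#'
#' @param genome Named `DNAStringSet`.
#' @param genes `GRanges` gene models with `gene_id`.
#' @param truth `GRanges` of truth regions (defines the target genes).
#' @param pattern IUPAC consensus string.
#' @param rate Expected planted sites per target gene.
#' @param seed RNG seed (defaults derive from nothing here; pass
#'   `stage_seed()`-derived value or a `sim_config` seed).
#' @return List with `genome` (modified copy) and `sites` (`GRanges` with
#'   `strand`, `pattern`, `site_seq` metadata; width = pattern length).
#' @export
embed_motifs <- function(genome, genes, truth, pattern, rate, seed = 1L) {
  iupac_check(pattern)
  if (rate < 0) stop("rate must be >= 0")
  m <- nchar(pattern)
  if (length(genes) > 0L && m > min(width(genes)))
    stop("pattern longer than the shortest gene")
  target_ids <- unique(truth$gene_id)
  targets <- genes[genes$gene_id %in% target_ids]
  empty_sites <- GRanges(seqnames = character(0), IRanges(),
                         strand = character(0))
  if (rate == 0 || length(targets) == 0L) {
    empty_sites <- set_genome_info(empty_sites, chrom_lengths_of(genome))
    empty_sites$pattern <- character(0)
    empty_sites$site_seq <- character(0)
    return(list(genome = genome, sites = empty_sites))
  }
  withr::with_seed(seed, {
    out_genome <- genome
    recs <- list()
    for (i in seq_along(targets)) {
      g <- targets[i]
      k <- rpois(1L, rate)
      if (k == 0L) next
      # non-overlapping placements inside [start, end - m + 1]
      chosen <- IRanges()
      tries <- 0L
      while (length(chosen) < k && tries < 200L * k) {
        tries <- tries + 1L
        s <- start(g) + sample.int(width(g) - m + 1L, 1L) - 1L
        cand <- IRanges(start = s, width = m)
        if (countOverlaps(cand, chosen) == 0L) chosen <- c(chosen, cand)
      }
      if (length(chosen) < k)
        warning("placed only ", length(chosen), "/", k,
                " motifs in gene ", g$gene_id)
      for (j in seq_along(chosen)) {
        inst <- iupac_instantiate(pattern)
        strand_j <- sample(c("+", "-"), 1L)
        written <- if (strand_j == "+") inst else revcomp(inst)
        ch <- as.character(seqnames(g))
        Biostrings::subseq(out_genome[[ch]],
                           start = start(chosen)[j], width = m) <-
          Biostrings::DNAString(written)
        recs[[length(recs) + 1L]] <- data.table(
          chrom = ch, start = start(chosen)[j], strand = strand_j,
          site_seq = inst, gene_id = g$gene_id)
      }
    }
    if (length(recs) == 0L) {
      empty_sites <- set_genome_info(empty_sites, chrom_lengths_of(genome))
      empty_sites$pattern <- character(0)
      empty_sites$site_seq <- character(0)
      return(list(genome = out_genome, sites = empty_sites))
    }
    dt <- data.table::rbindlist(recs)
    sites <- GRanges(dt$chrom, IRanges(start = dt$start, width = m),
                     strand = dt$strand)
    sites$pattern <- pattern
    sites$site_seq <- dt$site_seq
    sites$gene_id <- dt$gene_id
    sites <- set_genome_info(sites, chrom_lengths_of(genome))
    list(genome = out_genome, sites = sort(sites, ignore.strand = TRUE))
  })
}

# Draw one concrete sequence from an IUPAC consensus (ambiguity codes
# resolved uniformly at random).
iupac_instantiate <- function(pattern) {
  sets <- iupac_base_sets()
  paste(vapply(strsplit(pattern, "")[[1]], function(ch) {
    opts <- sets[[ch]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

#' Sample an up-regulated gene list with group-specific rates
#'
#' Emulates a differential-expression call set: each gene in `groups[[i]]`
#' is declared up-regulated independently with probability `rates[i]`.
#' Used to exercise the expression-integration operations against a known
#' truth.
#'
#' @param groups Named list of character vectors of gene ids.
#' @param rates Numeric vector of up-regulation probabilities, one per
#'   group.
#' @param seed RNG seed.
#' @return Character vector of up-regulated gene ids.
#' @export
simulate_up_genes <- function(groups, rates, seed = 1L) {
  stopifnot(length(groups) == length(rates), all(rates >= 0 & rates <= 1))
  withr::with_seed(seed, {
    unlist(lapply(seq_along(groups), function(i) {
      g <- groups[[i]]
      g[runif(length(g)) < rates[i]]
    }), use.names = FALSE)
  })
}
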