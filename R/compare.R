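#' Classify two peak sets by co-location
#'
#' A peak from set A co-locates with set B when the two intervals share at
#' least 1 bp (half-open interval intersection of positive length).
#' Every A peak is classified as AB or A-only, every B peak as AB or
#' B-only; an A peak overlapping several B peaks counts once.
#'
#' @param peaks_a,peaks_b `GRanges` peak sets on the same genome.
#' @return A `coloc_result`: list with counts `n_a`, `n_b`, `n_ab`
#'   (A-side co-located), `n_a_only`, `n_b_ab` (B-side co-located),
#'   `n_b_only`, logical vectors `a_hit`/`b_hit`, and the overlapping
#'   `pairs` (data.table of A/B indices).
#' @export
categorize_overlap <- function(peaks_a, peaks_b) {
  hits <- findOverlaps(peaks_a, peaks_b, minoverlap = 1L,
                       ignore.strand = TRUE)
  a_hit <- seq_along(peaks_a) %in% queryHits(hits)
  b_hit <- seq_along(peaks_b) %in% subjectHits(hits)
  structure(list(
    n_a = length(peaks_a), n_b = length(peaks_b),
    n_ab = sum(a_hit), n_a_only = sum(!a_hit),
    n_b_ab = sum(b_hit), n_b_only = sum(!b_hit),
    a_hit = a_hit, b_hit = b_hit,
    pairs = data.table(a = queryHits(hits), b = subjectHits(hits))),
    class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("co-location: |A| =", x$n_a, "(", x$n_ab, "co-located,", x$n_a_only,
      "A-only ); |B| =", x$n_b, "(", x$n_b_ab, "co-located,", x$n_b_only,
      "B-only )\n")
  invisible(x)
}

#' Assign peaks to the genes they overlap
#'
#' A peak is assigned to every gene whose extent, widened by `flank` bp on
#' both sides, it overlaps by at least 1 bp; a peak spanning several genes
#' contributes to all of them. Peaks on chromosomes absent from the
#' annotation raise a warning and stay unassigned.
#'
#' @param peaks `GRanges` of peaks.
#' @param genes `GRanges` of gene models with `gene_id`.
#' @param flank Flank in bp added to each gene extent (default 0: gene
#'   body only).
#' @return List with `genes` (character vector, the union of assigned
#'   gene ids), `map` (data.table of `peak` index / `gene_id` pairs) and
#'   `peak_genes` (list of gene-id vectors, one per peak).
#' @export
assign_peaks_to_genes <- function(peaks, genes, flank = 0L) {
  if (flank < 0L) stop("flank must be >= 0")
  pk_chr <- as.character(seqnames(peaks))
  missing_chr <- setdiff(unique(pk_chr),
                         as.character(unique(seqnames(genes))))
  if (length(missing_chr) > 0L && length(peaks) > 0L) {
    warning("peaks on chromosomes absent from the annotation left ",
            "unassigned: ", paste(missing_chr, collapse = ", "))
  }
  ext <- genes
  if (flank > 0L) {
    ext <- GRanges(seqnames(genes),
                   IRanges(start = pmax(start(genes) - flank, 1L),
                           end = end(genes) + flank))
    ext$gene_id <- genes$gene_id
  }
  keep <- which(!pk_chr %in% missing_chr)
  if (length(keep) == 0L) {
    map <- data.table(peak = integer(0), gene_id = character(0))
  } else {
    pk <- peaks[keep]
    GenomeInfoDb::seqlevels(pk) <- as.character(unique(seqnames(pk)))
    hits <- findOverlaps(pk, ext, minoverlap = 1L, ignore.strand = TRUE)
    map <- data.table(peak = keep[queryHits(hits)],
                      gene_id = ext$gene_id[subjectHits(hits)])
  }
  peak_genes <- split(map$gene_id, factor(map$peak,
                                          levels = seq_along(peaks)))
  list(genes = unique(map$gene_id), map = map,
       peak_genes = unname(peak_genes))
}

#' Histogram of peak sizes in fixed-width bins
#'
#' Peak length is `end - start` (half-open); a peak falls in bin
#' `floor(length / bin_width)`.
#'
#' @param peaks `GRanges` of peaks.
#' @param bin_width Bin width in bp (default 200).
#' @return data.table with `bin_start`, `bin_end`, `count` for every
#'   occupied bin range (zero-count bins up to the maximum included).
#' @export
peak_size_histogram <- function(peaks, bin_width = 200L) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (length(peaks) == 0L) {
    return(data.table(bin_start = integer(0), bin_end = integer(0),
                      count = integer(0)))
  }
  idx <- width(peaks) %/% as.integer(bin_width)
  tab <- tabulate(idx + 1L, nbins = max(idx) + 1L)
  data.table(bin_start = (seq_along(tab) - 1L) * as.integer(bin_width),
             bin_end = seq_along(tab) * as.integer(bin_width),
             count = tab)
}

#' Compare two gene sets
#'
#' Exact set algebra on gene identifiers, with the shared percentage
#' expressed relative to set A: `100 * |A intersect B| / |A|`.
#'
#' @param set_a,set_b Character vectors of gene ids (de-duplicated
#'   internally).
#' @return List with `overlap`, `a_only`, `b_only` (counts), the
#'   corresponding id vectors, and `percent_a`.
#' @export
compare_gene_sets <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) == 0L)
    stop("set A is empty: shared percentage undefined")
  shared <- intersect(a, b)
  list(overlap = length(shared),
       a_only = length(setdiff(a, b)),
       b_only = length(setdiff(b, a)),
       shared_ids = shared,
       a_only_ids = setdiff(a, b),
       b_only_ids = setdiff(b, a),
       percent_a = 100 * length(shared) / length(a))
}

#' Fraction of a peak-gene group that is up-regulated
#'
#' `|peak_genes intersect up_genes| / |peak_genes|`. Used to compare how
#' often genes in different peak categories (e.g. co-located-mark genes
#' vs single-mark genes) are de-repressed in Polycomb-mutant expression
#' data.
#'
#' @param peak_genes Character vector of gene ids in the group.
#' @param up_genes Character vector of up-regulated gene ids.
#' @return The fraction (scalar in `[0, 1]`).
#' @export
upregulated_fraction <- function(peak_genes, up_genes) {
  pg <- unique(peak_genes)
  if (length(pg) == 0L)
    stop("empty peak-gene group: fraction undefined")
  length(intersect(pg, unique(up_genes))) / length(pg)
}

#' Compare up-regulation between two peak-gene groups
#'
#' @param group1,group2 Character vectors of gene ids.
#' @param up_genes Character vector of up-regulated gene ids.
#' @return List with `fraction1`, `fraction2` and their `ratio`
#'   (fraction1 / fraction2; `Inf` if fraction2 is 0).
#' @export
upregulated_ratio <- function(group1, group2, up_genes) {
  f1 <- upregulated_fraction(group1, up_genes)
  f2 <- upregulated_fraction(group2, up_genes)
  list(fraction1 = f1, fraction2 = f2,
       ratio = if (f2 == 0) Inf else f1 / f2)
}

#' Hypergeometric category enrichment with BH correction
#'
#' For each category, tests whether the study set contains more annotated
#' genes than expected from drawing `n = |study|` genes without
#' replacement from the population: `p = P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)` (exact upper tail), with
#' Benjamini-Hochberg adjustment across the tested categories.
#' Categories with no annotated gene in the population are skipped with a
#' warning.
#'
#' @param study_set Character vector of gene ids (must be contained in
#'   `population`).
#' @param population Character vector of gene ids (the universe).
#' @param annotation Named list: category id -> character vector of
#'   annotated gene ids.
#' @return data.table with columns `category`, `k`, `n`, `K`, `N`, `p`,
#'   `q`, sorted by `p`.
#' @export
hypergeom_enrichment <- function(study_set, population, annotation) {
  study <- unique(study_set); pop <- unique(population)
  if (!all(study %in% pop))
    stop("study_set must be a subset of population")
  N <- length(pop); n <- length(study)
  rows <- lapply(names(annotation), function(cat) {
    ann <- intersect(unique(annotation[[cat]]), pop)
    K <- length(ann)
    if (K == 0L) return(NULL)
    k <- length(intersect(study, ann))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.table(category = cat, k = k, n = n, K = K, N = N, p = p)
  })
  skipped <- names(annotation)[vapply(rows, is.null, logical(1))]
  if (length(skipped) > 0L)
    warning("categories with no annotated population gene skipped: ",
            paste(skipped, collapse = ", "))
  dt <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(dt) == 0L) {
    dt$q <- numeric(0)
    return(dt)
  }
  dt$q <- bh_qvalues(dt$p)
  setorder(dt, p)
  dt
}
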