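#' Peak-calling configuration
#'
#' Parameters of the window-based enrichment caller. Defaults follow the
#' standard protocol for plant PRC2/H3K27me3 data: 10 bp windows, a
#' 3-fold enrichment threshold over input on the log2 ratio scale, merging
#' of candidate intervals separated by less than 200 bp, and a q-value
#' cutoff of 1e-10 chosen to maximize called peaks in treatment while
#' yielding none from input-vs-input comparisons.
#'
#' @param L Fragment extension length in bp (200 for protein ChIP, 150
#'   for the histone mark in the motivating datasets).
#' @param window_width Window width in bp.
#' @param fold_threshold Enrichment threshold on the natural scale;
#'   windows with `log2R >= log2(fold_threshold)` seed candidates.
#' @param merge_gap Candidates separated by fewer than this many bp are
#'   merged.
#' @param q_cutoff Benjamini-Hochberg q-value cutoff.
#' @param pseudocount Added to both normalized densities before the ratio
#'   (in per-million S units) to stabilize windows with zero control
#'   signal.
#' @return An object of class `peak_call_config`.
#' @export
peak_call_config <- function(L = 200L, window_width = 10L,
                             fold_threshold = 3, merge_gap = 200L,
                             q_cutoff = 1e-10, pseudocount = 1) {
  cfg <- list(L = as.integer(L), window_width = as.integer(window_width),
              fold_threshold = as.numeric(fold_threshold),
              merge_gap = as.integer(merge_gap),
              q_cutoff = as.numeric(q_cutoff),
              pseudocount = as.numeric(pseudocount))
  if (cfg$L <= 0L) stop("L must be positive")
  if (cfg$window_width <= 0L) stop("window_width must be positive")
  if (cfg$fold_threshold <= 1) stop("fold_threshold must exceed 1")
  if (cfg$merge_gap < 0L) stop("merge_gap must be >= 0")
  if (cfg$q_cutoff <= 0 || cfg$q_cutoff >= 1)
    stop("q_cutoff must lie in (0, 1)")
  if (cfg$pseudocount <= 0) stop("pseudocount must be positive")
  structure(cfg, class = "peak_call_config")
}

#' Per-window log2 enrichment ratio of two tracks
#'
#' `R = log2((S_treat + pseudocount) / (S_control + pseudocount))` per
#' window. Both tracks must share the genome, window grid and
#' normalization state.
#'
#' @param treat,control `window_track` objects on the same grid.
#' @param pseudocount Stabilizer added to both densities.
#' @return A `ratio_track` (same layout as a `window_track`; `S` holds R
#'   values).
#' @export
log2_ratio_track <- function(treat, control, pseudocount = 1) {
  stopifnot(inherits(treat, "window_track"),
            inherits(control, "window_track"))
  check_same_grid(treat, control)
  if (pseudocount <= 0) stop("pseudocount must be positive")
  S <- lapply(names(treat$S), function(ch) {
    log2((treat$S[[ch]] + pseudocount) / (control$S[[ch]] + pseudocount))
  })
  names(S) <- names(treat$S)
  structure(list(S = S, window_width = treat$window_width,
                 chrom_lengths = treat$chrom_lengths,
                 pseudocount = pseudocount),
            class = "ratio_track")
}

# Merge sorted intervals (per chromosome) separated by < gap bp, to a
# fixed point. dt: data.table(chrom, start, end) 1-based closed, sorted.
merge_within_gap <- function(dt, gap) {
  if (nrow(dt) <= 1L) return(dt)
  out <- list()
  cur <- dt[1]
  for (i in 2L:nrow(dt)) {
    row <- dt[i]
    same <- row$chrom == cur$chrom
    # bp gap between [.., cur$end] and [row$start, ..] is row$start - cur$end - 1
    if (same && (row$start - cur$end - 1L) < gap) {
      cur$end <- max(cur$end, row$end)
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- row
    }
  }
  out[[length(out) + 1L]] <- cur
  data.table::rbindlist(out)
}

#' Form candidate peaks from an enrichment ratio track
#'
#' Maximal runs of windows with `R >= log2(fold_threshold)` become
#' intervals; intervals separated by fewer than `merge_gap` bp are merged
#' iteratively to a fixed point. Each candidate carries the fragment
#' counts of both samples over the final interval (overlap >= 1 bp) and
#' the maximum windowed log2 ratio within it.
#'
#' @param ratio A `ratio_track` from [log2_ratio_track()].
#' @param fragments_treat,fragments_control `GRanges` of extended
#'   fragments.
#' @param cfg A [peak_call_config()].
#' @return `GRanges` of candidates with metadata `k_treat`, `k_control`,
#'   `max_log2R`; empty when no window passes the threshold.
#' @export
call_candidates <- function(ratio, fragments_treat, fragments_control,
                            cfg) {
  stopifnot(inherits(ratio, "ratio_track"),
            inherits(cfg, "peak_call_config"))
  thr <- log2(cfg$fold_threshold)
  w <- ratio$window_width
  runs <- lapply(names(ratio$S), function(ch) {
    above <- ratio$S[[ch]] >= thr
    if (!any(above)) return(NULL)
    r <- rle(above)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    keep <- r$values
    # window i (1-based) spans bp [(i-1)*w + 1, i*w] (1-based closed)
    data.table(chrom = ch,
               start = (starts_idx[keep] - 1L) * w + 1L,
               end = pmin(ends_idx[keep] * w,
                          ratio$chrom_lengths[[ch]]))
  })
  dt <- data.table::rbindlist(runs[!vapply(runs, is.null, logical(1))])
  empty <- GRanges(seqnames = character(0), IRanges())
  empty <- set_genome_info(empty, ratio$chrom_lengths)
  empty$k_treat <- integer(0); empty$k_control <- integer(0)
  empty$max_log2R <- numeric(0)
  if (nrow(dt) == 0L) return(empty)
  setorder(dt, chrom, start)
  repeat {
    merged <- merge_within_gap(dt, cfg$merge_gap)
    if (nrow(merged) == nrow(dt)) break
    dt <- merged
  }
  gr <- GRanges(dt$chrom, IRanges(start = dt$start, end = dt$end))
  gr <- set_genome_info(gr, ratio$chrom_lengths)
  gr$k_treat <- countOverlaps(gr, fragments_treat, minoverlap = 1L)
  gr$k_control <- countOverlaps(gr, fragments_control, minoverlap = 1L)
  gr$max_log2R <- vapply(seq_along(gr), function(i) {
    ch <- as.character(seqnames(gr))[i]
    wi <- ((start(gr)[i] - 1L) %/% w + 1L):((end(gr)[i] - 1L) %/% w + 1L)
    max(ratio$S[[ch]][wi])
  }, numeric(1))
  gr
}

#' One-sided exact binomial enrichment test for a candidate peak
#'
#' Tests whether the treatment share of the `n = k_treat + k_control`
#' fragments in a candidate exceeds the library-size expectation. Under
#' the null, each of the n fragments is a treatment fragment with
#' probability `p0 = N_treat / (N_treat + N_control)` (0.5 at equal
#' depth), and `p = P(X >= k_treat)` for `X ~ Binomial(n, p0)`, the exact
#' upper tail.
#'
#' @param k_treat,k_control Fragment counts in the candidate (vectors
#'   allowed).
#' @param N_treat,N_control Library sizes (total fragments).
#' @return Vector of exact one-sided p-values.
#' @examples
#' binomial_peak_test(10, 0, 1e6, 1e6)  # 0.5^10
#' @export
binomial_peak_test <- function(k_treat, k_control, N_treat, N_control) {
  if (N_treat < 1 || N_control < 1) stop("library sizes must be >= 1")
  n <- k_treat + k_control
  if (any(n < 1)) stop("candidate with no fragments: test undefined")
  p0 <- N_treat / (N_treat + N_control)
  pbinom(k_treat - 1, n, p0, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjusted q-values
#'
#' Standard BH adjustment: sort p ascending, take
#' `q_(i) = min_{j >= i} p_(j) * m / j` capped at 1, return in the input
#' order. Controls the false discovery rate for independent or positively
#' dependent tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_qvalues <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call significant enrichment peaks from two read sets
#'
#' The full caller: extend reads of both samples to fragments, build
#' per-million-normalized window density tracks, form the log2
#' treatment/control ratio, threshold-and-merge candidate intervals,
#' score each candidate with the exact binomial test, adjust with
#' Benjamini-Hochberg, and keep peaks with `q <= q_cutoff`. Output is
#' sorted by chromosome then start; merged formation guarantees no two
#' peaks are separated by less than `merge_gap` bp.
#'
#' @param reads_treat,reads_control `GRanges` of width-1 stranded read 5'
#'   positions.
#' @param genome Chromosome lengths (named vector, `DNAStringSet`, or
#'   `GRanges` with seqlengths).
#' @param cfg A [peak_call_config()].
#' @param keep_candidates Also return unfiltered scored candidates
#'   (attribute `"candidates"`)?
#' @return `GRanges` of peaks with metadata `k_treat`, `k_control`,
#'   `max_log2R`, `p`, `q`.
#' @export
call_peaks <- function(reads_treat, reads_control, genome,
                       cfg = peak_call_config(), keep_candidates = FALSE) {
  stopifnot(inherits(cfg, "peak_call_config"))
  if (length(reads_treat) == 0L || length(reads_control) == 0L)
    stop("both samples must contain reads")
  clens <- chrom_lengths_of(genome)
  ft <- extend_reads(reads_treat, cfg$L, clens)
  fc <- extend_reads(reads_control, cfg$L, clens)
  st <- window_density(ft, clens, cfg$window_width, normalize = TRUE)
  sc <- window_density(fc, clens, cfg$window_width, normalize = TRUE)
  ratio <- log2_ratio_track(st, sc, cfg$pseudocount)
  cand <- call_candidates(ratio, ft, fc, cfg)
  if (length(cand) == 0L) {
    cand$p <- numeric(0); cand$q <- numeric(0)
    if (keep_candidates) attr(cand, "candidates") <- cand
    return(cand)
  }
  cand$p <- binomial_peak_test(cand$k_treat, cand$k_control,
                               length(ft), length(fc))
  cand$q <- bh_qvalues(cand$p)
  out <- sort(cand[cand$q <= cfg$q_cutoff], ignore.strand = TRUE)
  if (keep_candidates) attr(out, "candidates") <- cand
  out
}
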