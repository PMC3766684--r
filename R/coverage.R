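#' Extend read 5' positions into fixed-length fragments
#'
#' Reconstructs the sequenced fragment from each read's 5'-most base: a
#' plus-strand read at 0-based position p becomes the interval
#' `[p, p + L)`, a minus-strand read at p becomes `[p - L + 1, p + 1)`
#' (the fragment extends 3'-ward from the 5' base on either strand).
#' Fragments are clipped at chromosome edges, so after clipping
#' `width <= L` with equality away from the edges.
#'
#' @param reads `GRanges` of width-1 read 5' positions with strand.
#' @param L Fragment length in bp (e.g. 200 for a protein-ChIP library,
#'   150 for a histone-mark library).
#' @param chrom_lengths Named vector of chromosome lengths (or any object
#'   accepted by the genome argument of [window_density()]).
#' @return `GRanges` of fragments (strand dropped), seqlengths set.
#' @examples
#' r <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(start = 1001, width = 1), strand = "+")
#' extend_reads(r, L = 200, chrom_lengths = c(chr1 = 1e5))
#' @export
extend_reads <- function(reads, L, chrom_lengths) {
  if (length(L) != 1L || L <= 0) stop("L must be a positive scalar")
  clens <- chrom_lengths_of(chrom_lengths)
  check_reads_in_bounds(reads, clens)
  str <- as.character(strand(reads))
  if (any(str == "*")) stop("reads must be stranded (+/-)")
  p <- start(reads)  # 1-based 5' base
  s <- ifelse(str == "+", p, p - L + 1L)
  e <- ifelse(str == "+", p + L - 1L, p)
  chr <- as.character(seqnames(reads))
  s <- pmax(s, 1L)
  e <- pmin(e, clens[chr])
  frag <- GRanges(chr, IRanges(start = s, end = e), strand = "*")
  frag <- set_genome_info(frag, clens)
  frag
}

#' Normalized fragment density on fixed-width windows
#'
#' Tiles each chromosome with `window_width`-bp windows starting at
#' coordinate 0 (the last partial window is kept) and counts, for every
#' window, the fragments overlapping it by at least 1 bp. With
#' `normalize = TRUE` counts are scaled to reads-per-million:
#' `S = raw * 1e6 / library_size`, making treatment and control tracks
#' comparable across sequencing depths.
#'
#' @param fragments `GRanges` of extended fragments.
#' @param genome Chromosome lengths (named vector, `DNAStringSet`, or
#'   `GRanges` with seqlengths).
#' @param window_width Window width in bp (default 10).
#' @param normalize Scale counts to per-million library size?
#' @return A `window_track`: list with `S` (named list of per-chromosome
#'   numeric vectors of length `ceiling(chrom_length / window_width)`),
#'   `window_width`, `chrom_lengths`, `library_size`, `scale`,
#'   `normalized`.
#' @export
window_density <- function(fragments, genome, window_width = 10L,
                           normalize = TRUE) {
  if (window_width <= 0) stop("window_width must be positive")
  clens <- chrom_lengths_of(genome)
  lib <- length(fragments)
  scale <- NA_real_
  if (normalize) {
    if (lib == 0L) {
      warning("empty fragment set: normalization scale undefined, ",
              "returning zero track")
    } else {
      scale <- 1e6 / lib
    }
  }
  w <- as.integer(window_width)
  chr <- as.character(seqnames(fragments))
  S <- lapply(names(clens), function(ch) {
    n_win <- as.integer(ceiling(clens[[ch]] / w))
    counts <- numeric(n_win)
    sel <- chr == ch
    if (any(sel)) {
      # window index of a 1-based bp b is (b - 1) %/% w (0-based index)
      first <- (start(fragments)[sel] - 1L) %/% w
      last <- (end(fragments)[sel] - 1L) %/% w
      # difference-array accumulation: +1 at first, -1 after last
      delta <- numeric(n_win + 1L)
      tf <- tabulate(first + 1L, nbins = n_win)
      tl <- tabulate(last + 2L, nbins = n_win + 1L)
      delta[seq_len(n_win)] <- delta[seq_len(n_win)] + tf
      delta <- delta - tl
      counts <- cumsum(delta[seq_len(n_win)])
    }
    if (normalize && !is.na(scale)) counts * scale else counts
  })
  names(S) <- names(clens)
  structure(list(S = S, window_width = w, chrom_lengths = clens,
                 library_size = lib, scale = scale,
                 normalized = normalize),
            class = "window_track")
}

#' @export
print.window_track <- function(x, ...) {
  cat("window_track:", length(x$S), "chromosome(s),", x$window_width,
      "bp windows, library_size", x$library_size,
      if (x$normalized) "(per-million normalized)" else "(raw counts)",
      "\n")
  invisible(x)
}

# Shared grid check for two tracks.
check_same_grid <- function(a, b) {
  if (!identical(a$window_width, b$window_width) ||
      !identical(a$chrom_lengths, b$chrom_lengths))
    stop("tracks are on different window grids")
  if (!identical(a$normalized, b$normalized))
    stop("tracks differ in normalization")
  invisible(TRUE)
}
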