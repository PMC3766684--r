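# IUPAC nucleotide ambiguity alphabet.
iupac_base_sets <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
       W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
       B = c("C", "G", "T"), D = c("A", "G", "T"),
       H = c("A", "C", "T"), V = c("A", "C", "G"),
       N = c("A", "C", "G", "T"))
}

iupac_check <- function(pattern) {
  if (length(pattern) != 1L || !is.character(pattern))
    stop("pattern must be a single string")
  if (nchar(pattern) < 4L)
    stop("pattern must be at least 4 nucleotides long")
  ch <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(ch, names(iupac_base_sets()))
  if (length(bad) > 0L)
    stop("invalid IUPAC code(s): ", paste(unique(bad), collapse = ", "))
  invisible(TRUE)
}

#' Reverse complement of an IUPAC string
#' @param x A nucleotide string (ambiguity codes allowed).
#' @return The reverse complement, ambiguity codes mapped correctly
#'   (R<->Y, K<->M, B<->V, D<->H; S, W, N self-complementary).
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""),
         character(1))
}

# Bitmask encodings. Subject characters: A/C/G/T get their base bit; any
# other character gets a distinct bit that only pattern N matches.
subject_codes <- function(seq_chars) {
  code <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  out <- unname(code[seq_chars])
  out[is.na(out)] <- 16L
  out
}

pattern_masks <- function(pattern) {
  base_bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  sets <- iupac_base_sets()
  vapply(strsplit(toupper(pattern), "")[[1]], function(ch) {
    m <- sum(base_bit[sets[[ch]]])
    if (ch == "N") m <- m + 16L  # N also matches non-ACGT characters
    as.integer(m)
  }, integer(1))
}

# All forward match start positions (1-based) of an IUPAC pattern in one
# sequence, overlapping matches included.
scan_one_strand <- function(codes, pmask) {
  n <- length(codes); m <- length(pmask)
  if (n < m) return(integer(0))
  hit <- rep(TRUE, n - m + 1L)
  for (j in seq_len(m)) {
    hit <- hit & bitwAnd(codes[j:(n - m + j)], pmask[j]) > 0L
  }
  which(hit)
}

#' Scan sequences for an IUPAC consensus motif
#'
#' Reports every position (overlapping matches included) where the
#' sequence matches the pattern under IUPAC semantics; with
#' `both_strands`, positions matching the reverse complement of the
#' pattern are also reported, on the minus strand with forward
#' coordinates. Non-ACGT sequence characters match only pattern `N`.
#' A palindromic match at one locus is reported once per strand;
#' [motif_positional_distribution()] de-duplicates by midpoint and
#' pattern.
#'
#' @param x Sequences: a named `DNAStringSet`, a named character vector,
#'   or a single unnamed string (named `"seq1"`).
#' @param pattern IUPAC consensus (length >= 4).
#' @param both_strands Also scan the reverse complement?
#' @param name Pattern name recorded on hits (defaults to the pattern).
#' @return `GRanges` of hits (width = pattern length) with `pattern`
#'   metadata, sorted by sequence then start.
#' @examples
#' scan_motif(c(s = "GAGAGAG"), "GAGAG", both_strands = FALSE)
#' @export
scan_motif <- function(x, pattern, both_strands = TRUE, name = pattern) {
  iupac_check(pattern)
  if (is(x, "DNAStringSet")) {
    seqs <- as.character(x)
  } else if (is.character(x)) {
    seqs <- x
    if (is.null(names(seqs)) && length(seqs) == 1L) names(seqs) <- "seq1"
  } else {
    stop("x must be a DNAStringSet or character vector")
  }
  if (is.null(names(seqs))) stop("sequences must be named")
  m <- nchar(pattern)
  fwd_mask <- pattern_masks(pattern)
  rev_mask <- if (both_strands) pattern_masks(revcomp(pattern)) else NULL
  rows <- lapply(names(seqs), function(sn) {
    codes <- subject_codes(strsplit(toupper(seqs[[sn]]), "")[[1]])
    pos_f <- scan_one_strand(codes, fwd_mask)
    pos_r <- if (both_strands) scan_one_strand(codes, rev_mask) else
      integer(0)
    data.table(chrom = sn,
               start = c(pos_f, pos_r),
               strand = rep(c("+", "-"), c(length(pos_f), length(pos_r))))
  })
  dt <- data.table::rbindlist(rows)
  if (nrow(dt) == 0L) {
    gr <- GRanges(seqnames = character(0), IRanges(),
                  strand = character(0))
    gr$pattern <- character(0)
    return(gr)
  }
  setorder(dt, chrom, start, strand)
  gr <- GRanges(dt$chrom, IRanges(start = dt$start, width = m),
                strand = dt$strand)
  gr$pattern <- name
  gr
}

#' Extract peak sequences from a genome
#'
#' One FASTA-ready record per peak, named `chrom:start-end` in 0-based
#' half-open coordinates, uppercased, an exact substring of the genome.
#' Peaks running past a chromosome end are clipped with a warning.
#' Intended to feed external de-novo motif discovery.
#'
#' @param peaks `GRanges` of peaks.
#' @param genome Named `DNAStringSet`.
#' @return Named `DNAStringSet`, one record per peak, in input order.
#' @export
extract_peak_sequences <- function(peaks, genome) {
  clens <- chrom_lengths_of(genome)
  chr <- as.character(seqnames(peaks))
  if (!all(chr %in% names(clens)))
    stop("peaks on chromosomes absent from the genome")
  s <- start(peaks); e <- end(peaks)
  if (any(s < 1L) || any(e > clens[chr])) {
    warning("peak(s) beyond chromosome ends clipped")
    s <- pmax(s, 1L)
    e <- pmin(e, clens[chr])
  }
  out <- Biostrings::DNAStringSet(vapply(seq_along(peaks), function(i) {
    toupper(as.character(Biostrings::subseq(genome[[chr[i]]],
                                            start = s[i], end = e[i])))
  }, character(1)))
  names(out) <- sprintf("%s:%d-%d", chr, s - 1L, e)
  out
}
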