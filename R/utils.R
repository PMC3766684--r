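#' @importFrom methods is
#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqnames
#' @importFrom data.table data.table fread fwrite setorder :=
#' @importFrom stats pbinom phyper p.adjust rpois runif
NULL

# Derive a per-stage RNG seed from a master seed. Keeps substreams
# reproducible independently of call order; result stays below 2^31.
stage_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  offsets <- c(genome = 101L, genes = 211L, truth = 307L, reads_treatment = 401L,
               reads_input = 409L, motifs = 503L, expression = 601L)
  if (!stage %in% names(offsets)) {
    stop("unknown RNG stage: ", stage)
  }
  (as.integer(master_seed) %% 1000003L) * 2011L + offsets[[stage]]
}

#' Chromosome lengths of a genome-like object
#'
#' Accepts a named numeric vector (returned unchanged), a `DNAStringSet`
#' (sequence widths), or a `GRanges` with seqlengths set.
#' @param genome The object to interpret.
#' @return Named vector of chromosome lengths in bp.
#' @export
chrom_lengths_of <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else if (is(genome, "GRanges")) {
    sl <- seqlengths(genome)
    if (any(is.na(sl))) stop("GRanges has no seqlengths")
    sl
  } else if (is.numeric(genome) && !is.null(names(genome))) {
    genome
  } else {
    stop("cannot interpret chromosome lengths from object of class ",
         class(genome)[1])
  }
}

#' Validate read positions against chromosome bounds
#'
#' @param reads `GRanges` of width-1 read 5' positions.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @return Invisibly `TRUE`; signals an error for out-of-bounds reads.
#' @keywords internal
check_reads_in_bounds <- function(reads, chrom_lengths) {
  chr <- as.character(seqnames(reads))
  bad_chr <- !chr %in% names(chrom_lengths)
  if (any(bad_chr)) {
    stop("reads on chromosomes absent from the genome: ",
         paste(unique(chr[bad_chr]), collapse = ", "))
  }
  if (any(start(reads) < 1L) || any(start(reads) > chrom_lengths[chr])) {
    stop("read 5' positions outside chromosome bounds")
  }
  invisible(TRUE)
}

# Align a GRanges to the full genome: all chromosomes as seqlevels with
# their lengths, regardless of which chromosomes carry ranges.
set_genome_info <- function(gr, chrom_lengths) {
  GenomeInfoDb::seqlevels(gr) <- names(chrom_lengths)
  GenomeInfoDb::seqlengths(gr) <- chrom_lengths
  gr
}
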