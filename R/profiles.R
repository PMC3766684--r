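# Oriented bin layout for one gene: fixed-width flank bins plus a
# length-scaled gene body. Returns a data.table with zone (upstream /
# body / downstream), bin (1-based, bin 1 always 5'-most), start/end
# (1-based closed bp) and valid (FALSE when a flank bin runs off the
# chromosome and must be dropped from averages).
gene_bins <- function(s, e, strand, flank_bp, n_body_bins, n_flank_bins,
                      chrom_len) {
  len <- e - s + 1L
  bb <- s + floor((0:n_body_bins) * len / n_body_bins)
  body <- data.table(zone = "body", bin = seq_len(n_body_bins),
                     start = bb[seq_len(n_body_bins)],
                     end = bb[-1L] - 1L, valid = TRUE)
  fb <- flank_bp %/% n_flank_bins
  j <- seq_len(n_flank_bins)
  left <- data.table(zone = "left", bin = j,
                     start = s - flank_bp + (j - 1L) * fb,
                     end = s - flank_bp + j * fb - 1L)
  right <- data.table(zone = "right", bin = j,
                      start = e + (j - 1L) * fb + 1L,
                      end = e + j * fb)
  left$valid <- left$start >= 1L & left$end <= chrom_len
  right$valid <- right$start >= 1L & right$end <= chrom_len
  if (strand == "-") {
    up <- right[rev(j)]; dn <- left[rev(j)]
    body <- body[rev(seq_len(n_body_bins))]
  } else {
    up <- left; dn <- right
  }
  up$zone <- "upstream"; up$bin <- j
  dn$zone <- "downstream"; dn$bin <- j
  body$bin <- seq_len(n_body_bins); body$zone <- "body"
  data.table::rbindlist(list(up, body, dn))
}

check_profile_args <- function(flank_bp, n_body_bins, n_flank_bins) {
  if (n_body_bins < 1L || n_flank_bins < 1L)
    stop("bin counts must be positive")
  if (flank_bp %% n_flank_bins != 0L)
    stop("flank_bp must be a multiple of n_flank_bins")
  invisible(TRUE)
}

new_metagene_profile <- function(sums, counts, n_genes, flank_bp,
                                 n_body_bins, n_flank_bins) {
  mean_or_zero <- function(s, n) ifelse(n > 0, s / pmax(n, 1), 0)
  structure(list(
    upstream = mean_or_zero(sums$up, counts$up),
    body = mean_or_zero(sums$body, counts$body),
    downstream = mean_or_zero(sums$down, counts$down),
    n_upstream = counts$up, n_body = counts$body,
    n_downstream = counts$down,
    n_genes = n_genes, flank_bp = flank_bp,
    n_body_bins = n_body_bins, n_flank_bins = n_flank_bins),
    class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("metagene_profile:", x$n_flank_bins, "flank bins x", x$flank_bp,
      "bp flanks,", x$n_body_bins, "body bins,", x$n_genes, "genes\n")
  invisible(x)
}

#' Metagene profile of window signal over scaled gene bodies
#'
#' For each gene the body `[start, end)` is divided into `n_body_bins`
#' equal spans and the mean track signal over each span is computed;
#' fixed flanks of `flank_bp` bp use `n_flank_bins` spans of
#' `flank_bp / n_flank_bins` bp. Minus-strand genes are reversed so bin 1
#' is always 5'-most. The profile is the per-bin mean over genes (each
#' gene weighted equally, so long genes do not dominate). Flank bins
#' clipped at chromosome ends are dropped from the average for those
#' genes; genes shorter than `n_body_bins` bp are skipped with a warning.
#'
#' @param track A `window_track` (or `ratio_track`).
#' @param genes `GRanges` of gene models.
#' @param flank_bp Flank width in bp (must divide evenly by
#'   `n_flank_bins`).
#' @param n_body_bins,n_flank_bins Bin counts.
#' @return A `metagene_profile` with `upstream`, `body`, `downstream`
#'   mean vectors and per-bin contributing-gene counts.
#' @export
metagene_signal <- function(track, genes, flank_bp = 1000L,
                            n_body_bins = 40L, n_flank_bins = 20L) {
  stopifnot(inherits(track, c("window_track", "ratio_track")))
  check_profile_args(flank_bp, n_body_bins, n_flank_bins)
  if (length(genes) == 0L) stop("genes must be non-empty")
  w <- track$window_width
  short <- width(genes) < n_body_bins
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than n_body_bins bp skipped")
    genes <- genes[!short]
  }
  sums <- list(up = numeric(n_flank_bins), body = numeric(n_body_bins),
               down = numeric(n_flank_bins))
  counts <- list(up = integer(n_flank_bins), body = integer(n_body_bins),
                 down = integer(n_flank_bins))
  for (i in seq_along(genes)) {
    ch <- as.character(seqnames(genes))[i]
    if (!ch %in% names(track$S)) next
    vals <- track$S[[ch]]
    clen <- track$chrom_lengths[[ch]]
    bins <- gene_bins(start(genes)[i], end(genes)[i],
                      as.character(strand(genes))[i],
                      as.integer(flank_bp), n_body_bins, n_flank_bins,
                      clen)
    for (r in seq_len(nrow(bins))) {
      if (!bins$valid[r]) next
      bp <- bins$start[r]:bins$end[r]
      m <- mean(vals[(bp - 1L) %/% w + 1L])
      zone <- switch(bins$zone[r], upstream = "up", body = "body",
                     downstream = "down")
      sums[[zone]][bins$bin[r]] <- sums[[zone]][bins$bin[r]] + m
      counts[[zone]][bins$bin[r]] <- counts[[zone]][bins$bin[r]] + 1L
    }
  }
  new_metagene_profile(sums, counts, length(genes), as.integer(flank_bp),
                       n_body_bins, n_flank_bins)
}

#' Positional distribution of motif hits over scaled gene bodies
#'
#' Maps each hit's midpoint to a bin of every gene (plus flanks) that
#' contains it, using the same oriented bin layout as
#' [metagene_signal()]. Hits are first de-duplicated by chromosome,
#' midpoint and pattern (so a palindromic match reported on both strands
#' counts once). Per gene, bin counts are divided by the bin width in bp
#' (a density per bp); the profile is the per-bin mean over all genes,
#' genes without hits contributing zeros. Hits outside every gene-flank
#' extent are tallied in the `discarded` attribute, not an error.
#'
#' @param hits `GRanges` of motif hits (see [scan_motif()]).
#' @param genes `GRanges` of gene models.
#' @param flank_bp,n_body_bins,n_flank_bins As in [metagene_signal()].
#' @return A `metagene_profile` (values are mean hits per bp per gene)
#'   with attribute `discarded` (count of hits assigned to no gene).
#' @export
motif_positional_distribution <- function(hits, genes, flank_bp = 1000L,
                                          n_body_bins = 40L,
                                          n_flank_bins = 20L) {
  check_profile_args(flank_bp, n_body_bins, n_flank_bins)
  if (length(genes) == 0L) stop("genes must be non-empty")
  short <- width(genes) < n_body_bins
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than n_body_bins bp skipped")
    genes <- genes[!short]
  }
  # midpoint of 0-based half-open [s0, e0) is floor((s0 + e0) / 2)
  mid0 <- (start(hits) - 1L + end(hits)) %/% 2L
  pat <- if (!is.null(hits$pattern)) hits$pattern else
    rep(".", length(hits))
  dt <- unique(data.table(chrom = as.character(seqnames(hits)),
                          mid = mid0 + 1L, pattern = pat))
  sums <- list(up = numeric(n_flank_bins), body = numeric(n_body_bins),
               down = numeric(n_flank_bins))
  counts <- list(up = integer(n_flank_bins), body = integer(n_body_bins),
                 down = integer(n_flank_bins))
  assigned <- rep(FALSE, nrow(dt))
  clens <- if (!anyNA(seqlengths(genes))) seqlengths(genes) else NULL
  for (i in seq_along(genes)) {
    ch <- as.character(seqnames(genes))[i]
    clen <- if (!is.null(clens) && ch %in% names(clens)) clens[[ch]] else
      .Machine$integer.max
    bins <- gene_bins(start(genes)[i], end(genes)[i],
                      as.character(strand(genes))[i],
                      as.integer(flank_bp), n_body_bins, n_flank_bins,
                      clen)
    on_chr <- which(dt$chrom == ch)
    for (r in seq_len(nrow(bins))) {
      zone <- switch(bins$zone[r], upstream = "up", body = "body",
                     downstream = "down")
      if (!bins$valid[r]) next
      counts[[zone]][bins$bin[r]] <- counts[[zone]][bins$bin[r]] + 1L
      in_bin <- on_chr[dt$mid[on_chr] >= bins$start[r] &
                         dt$mid[on_chr] <= bins$end[r]]
      if (length(in_bin) > 0L) {
        bw <- bins$end[r] - bins$start[r] + 1L
        sums[[zone]][bins$bin[r]] <- sums[[zone]][bins$bin[r]] +
          length(in_bin) / bw
        assigned[in_bin] <- TRUE
      }
    }
  }
  out <- new_metagene_profile(sums, counts, length(genes),
                              as.integer(flank_bp), n_body_bins,
                              n_flank_bins)
  attr(out, "discarded") <- sum(!assigned)
  out
}
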