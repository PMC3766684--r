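#' Recall and precision of called peaks against truth regions
#'
#' A truth region counts as recovered when any called peak overlaps it by
#' at least 1 bp; a called peak counts as true when it overlaps any truth
#' region by at least 1 bp.
#'
#' @param peaks `GRanges` of called peaks.
#' @param truth `GRanges` of truth enrichment regions.
#' @return List with `recall`, `precision`, `n_peaks`, `n_truth`,
#'   `n_truth_recovered`, `n_peaks_true`. `precision` is `NA` when no
#'   peak was called; `recall` is `NA` when there are no truth regions.
#' @export
truth_recovery <- function(peaks, truth) {
  n_rec <- if (length(truth) > 0L)
    sum(countOverlaps(truth, peaks, minoverlap = 1L,
                      ignore.strand = TRUE) > 0L) else 0L
  n_true <- if (length(peaks) > 0L)
    sum(countOverlaps(peaks, truth, minoverlap = 1L,
                      ignore.strand = TRUE) > 0L) else 0L
  list(recall = if (length(truth) > 0L) n_rec / length(truth) else NA_real_,
       precision = if (length(peaks) > 0L) n_true / length(peaks) else
         NA_real_,
       n_peaks = length(peaks), n_truth = length(truth),
       n_truth_recovered = n_rec, n_peaks_true = n_true)
}
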