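# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles (log-space combinatorial sums, explicit
# loops, all-pairs scans) and never call the implementation under test.

# Upper binomial tail P(X >= k), X ~ Binomial(n, p0), by direct summation.
oracle_binom_tail <- function(k, n, p0) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  j <- k:n
  sum(exp(lchoose(n, j) + j * log(p0) + (n - j) * log1p(-p0)))
}

# BH step-up from the definition: sort ascending, q_(i) = min_{j>=i} of
# p_(j) * (m/j), cap at 1, return in input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * (m / seq_len(m))
  for (i in rev(seq_len(m - 1))) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Upper hypergeometric tail P(X >= k) for k annotated among n drawn from
# a population of N with K annotated, by direct summation.
oracle_hyper_tail <- function(N, K, n, k) {
  if (k <= 0) return(1)
  hi <- min(n, K)
  if (k > hi) return(0)
  j <- k:hi
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# Quadratic per-window overlap count. frag_start/frag_end 1-based closed.
oracle_window_counts <- function(frag_start, frag_end, chrom_len, w) {
  n_win <- ceiling(chrom_len / w)
  counts <- integer(n_win)
  for (i in seq_len(n_win)) {
    ws <- (i - 1) * w + 1
    we <- min(i * w, chrom_len)
    counts[i] <- sum(frag_start <= we & frag_end >= ws)
  }
  counts
}

# All-pairs interval overlap (>= 1 bp), 1-based closed coordinates.
oracle_overlap_matrix <- function(sa, ea, ca, sb, eb, cb) {
  hit <- matrix(FALSE, length(sa), length(sb))
  for (i in seq_along(sa)) {
    for (j in seq_along(sb)) {
      hit[i, j] <- ca[i] == cb[j] && sa[i] <= eb[j] && ea[i] >= sb[j]
    }
  }
  hit
}

# Naive sliding-window IUPAC scan of one sequence (forward strand),
# character-set membership per position.
oracle_scan_forward <- function(seq, pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  sc <- strsplit(toupper(seq), "")[[1]]
  pc <- strsplit(toupper(pattern), "")[[1]]
  m <- length(pc)
  hits <- integer(0)
  for (i in seq_len(length(sc) - m + 1)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      s_ch <- sc[i + j - 1]
      ok <- if (s_ch %in% c("A", "C", "G", "T")) {
        s_ch %in% sets[[pc[j]]]
      } else {
        pc[j] == "N"  # non-ACGT matches only N
      }
      if (!ok) break
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

oracle_revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# Brute-force metagene recomputation for one window track: explicit
# per-gene, per-bin, per-bp loops mirroring the documented layout
# (floor body boundaries, fixed flank spans, 5'-orientation, clipped
# flank bins dropped).
oracle_metagene <- function(track, genes, flank_bp, nb, nf) {
  w <- track$window_width
  fb <- flank_bp %/% nf
  sums <- list(up = numeric(nf), body = numeric(nb), down = numeric(nf))
  cnts <- list(up = integer(nf), body = integer(nb), down = integer(nf))
  for (i in seq_along(genes)) {
    ch <- as.character(GenomeInfoDb::seqnames(genes))[i]
    vals <- track$S[[ch]]
    clen <- track$chrom_lengths[[ch]]
    s <- GenomicRanges::start(genes)[i]
    e <- GenomicRanges::end(genes)[i]
    minus <- as.character(BiocGenerics::strand(genes))[i] == "-"
    len <- e - s + 1
    value_at <- function(b) vals[(b - 1) %/% w + 1]
    # body bins, genome order then orient
    body_means <- numeric(nb)
    for (bi in seq_len(nb)) {
      b0 <- s + floor((bi - 1) * len / nb)
      b1 <- s + floor(bi * len / nb) - 1
      body_means[bi] <- mean(vapply(b0:b1, value_at, numeric(1)))
    }
    if (minus) body_means <- rev(body_means)
    sums$body <- sums$body + body_means
    cnts$body <- cnts$body + 1L
    # flanks
    for (fi in seq_len(nf)) {
      l0 <- s - flank_bp + (fi - 1) * fb; l1 <- l0 + fb - 1
      r0 <- e + (fi - 1) * fb + 1; r1 <- r0 + fb - 1
      lval <- if (l0 >= 1 && l1 <= clen)
        mean(vapply(l0:l1, value_at, numeric(1))) else NA
      rval <- if (r0 >= 1 && r1 <= clen)
        mean(vapply(r0:r1, value_at, numeric(1))) else NA
      if (!minus) {
        if (!is.na(lval)) { sums$up[fi] <- sums$up[fi] + lval
          cnts$up[fi] <- cnts$up[fi] + 1L }
        if (!is.na(rval)) { sums$down[fi] <- sums$down[fi] + rval
          cnts$down[fi] <- cnts$down[fi] + 1L }
      } else {
        if (!is.na(rval)) { sums$up[nf - fi + 1] <- sums$up[nf - fi + 1] +
          rval; cnts$up[nf - fi + 1] <- cnts$up[nf - fi + 1] + 1L }
        if (!is.na(lval)) { sums$down[nf - fi + 1] <-
          sums$down[nf - fi + 1] + lval
          cnts$down[nf - fi + 1] <- cnts$down[nf - fi + 1] + 1L }
      }
    }
  }
  list(upstream = ifelse(cnts$up > 0, sums$up / pmax(cnts$up, 1), 0),
       body = sums$body / cnts$body,
       downstream = ifelse(cnts$down > 0, sums$down / pmax(cnts$down, 1),
                           0))
}
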