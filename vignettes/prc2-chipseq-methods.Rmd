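---
title: "Window-based peak calling for plant PRC2 ChIP-seq: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based peak calling for plant PRC2 ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Polycomb Repressive Complex 2 (PRC2) deposits H3K27me3, the dominant
repressive chromatin mark of plants. Locating where PRC2 itself binds —
via ChIP-seq of a tagged FIE subunit, the ESC homolog present in every
Arabidopsis PRC2 complex — and relating those sites to the H3K27me3
landscape, to gene bodies, to GAGA-like sequence motifs and to
de-repression in PRC2 mutants requires a chain of analyses: peak calling
against an input control, two-mark co-location, peak-to-gene assignment,
metagene and motif positional profiling, gene-set comparison and category
enrichment. `prc2peaks` implements that chain as tested, reusable
functions, and ships a synthetic-data generator with known ground truth
so every stage can be validated quantitatively — something the real
datasets, lacking truth labels, cannot offer.

# The peak-calling model

Reads are reduced to their 5′-most base and extended to the expected
fragment length $L$ ($L = 200$ bp for the protein ChIP, $L = 150$ bp for
the native histone-mark ChIP, reflecting the different library
preparations). Each chromosome is tiled with 10 bp windows from
coordinate 0 (the last partial window is kept) and the window statistic
is

$$S_x = \frac{10^6}{N_x}\,\#\{\text{fragments of sample } x
\text{ overlapping the window by} \ge 1\text{ bp}\},$$

a reads-per-million normalized density that makes treatment and control
comparable across sequencing depths. The enrichment score per window is

$$\log_2 R = \log_2\frac{S_{\mathrm{treatment}} + c}
{S_{\mathrm{control}} + c},$$

with pseudocount $c$ (default 1 RPM-unit) guarding windows with zero
control signal. Maximal runs of windows with $\log_2 R \ge \log_2 3$
(3-fold enrichment over input) become candidate intervals, and intervals
separated by fewer than 200 bp are merged to a fixed point.

Each candidate is scored with a one-sided exact binomial test in the
PeakSeq style: of the $n = k_t + k_c$ fragments overlapping the
candidate, the treatment count $k_t$ is compared with
$X \sim \mathrm{Binomial}(n, p_0)$,
$p_0 = N_t / (N_t + N_c)$ (0.5 at equal depth), and
$p = P(X \ge k_t)$. Benjamini–Hochberg adjustment across candidates
yields q-values; peaks with $q \le 10^{-10}$ are reported. That stringent
cutoff is chosen to maximize peaks called from treatment while an
input-vs-input comparison yields none, which the null simulations below
confirm directly.

## Interpretation choices

Three readings of the procedure are not forced by its usual description
and are fixed here as documented choices:

* **"within a window" means overlap ≥ 1 bp**, not containment — a
  150–200 bp fragment can never be contained in a 10 bp window, so
  overlap is the only coherent reading. A fragment therefore contributes
  to every window it touches.
* **Normalization is per-million library scaling.** Any common scale
  works for the ratio; per-million keeps tracks browser-interpretable.
* **The binomial null pools treatment and control fragments** with
  $p_0$ from the library-size ratio. An alternative parameterization
  (expected treatment count from the input rate alone) changes little at
  equal depth; pooling is the documented default.

Other numerical details: candidate fragment counts use the same ≥ 1 bp
overlap rule as the density; BH ties are broken by stable input order
(no effect on values); the test is one-sided because the screen is for
treatment excess; merging is iterated to a fixed point, so no two
reported peaks lie closer than the merge gap.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not sequencing chemistry:

* **Genome and genes.** I.i.d. uniform A/C/G/T sequence; genes of
  1–5 kb placed without overlap on both strands by rejection sampling.
* **Truth regions.** Enrichment domains lie wholly inside gene bodies
  (the gene-body localization typical of plant PRC2/H3K27me3), one per
  gene per mark. A mark-B domain co-locates with its mark-A partner —
  taking the *identical* interval — with probability `coloc_prob`;
  identical intervals (rather than merely overlapping ones) make the
  expected co-location counts analytic. Non-co-located B domains go to
  genes unused by A, so the truth labels are unambiguous.
* **Reads.** Input reads are uniform over the genome with random strand
  — the simplest null consistent with using digested chromatin as
  control; no GC or mappability bias is modelled. Treatment reads mix
  the same uniform background with reads whose extended fragment lies
  inside a truth region, each region weighted by
  $(\mathrm{fold}-1)\times\mathrm{width}$, so within-region read density
  is `fold` times background and `fold = 1` reduces exactly to the
  uniform null. Emitted counts equal requested counts exactly.
* **Motifs.** Concrete instances of an IUPAC consensus (default
  `GAGAG`, a GAGA-element core) are planted at Poisson(`rate`) per
  target gene, uniformly within gene bodies, on random strands,
  non-overlapping; every planted site is recorded for recall
  measurement.
* **Determinism.** One master seed; each stage (sequence, genes, truth,
  each read library, motifs) draws from its own derived substream, so
  identical configurations reproduce byte-identical outputs and stages
  can be regenerated independently.

The defaults embody the study conditions exercised throughout the tests:
fold 10 for true domains (no quantitative fold is available for real
domains; 10 gives treatment densities comfortably above the 3-fold
calling threshold while leaving the binomial test real work at 0.1–0.2
reads/bp), co-location probability 0.8, domain lengths of order 1 kb,
and 2 × 10^5 reads per library over ~10^6 bp genomes. What the generator
deliberately omits — duplicate reads, paired ends, sequencing errors,
mappability structure, biased input — bounds what green tests mean:
they validate the statistical machinery and its calibration under the
model's own assumptions, not robustness to artifacts of real libraries.

# Downstream analyses

* **Co-location** classifies two peak sets by ≥ 1 bp half-open interval
  intersection; an A peak overlapping any B peak counts once, so
  AB + A-only partitions set A (and symmetrically B).
* **Gene assignment** maps a peak to every gene whose extent (flank
  configurable, default 0 — the most conservative reading of "assigned
  to genes") it overlaps by ≥ 1 bp. A peak spanning several genes
  contributes to all of them, avoiding arbitrary tie-breaks.
* **Metagene profiles** scale each gene body to 40 bins (per-bin mean of
  the window signal over the bin's base pairs) with 1 kb flanks in 20
  fixed 50 bp bins; minus-strand genes are reversed so bin 1 is always
  5′. Genes are weighted equally (per-gene mean before the cross-gene
  mean) so long genes do not dominate; flank bins running off a
  chromosome are dropped from that gene's average; genes shorter than
  the bin count are skipped with a warning. The binning defaults are
  package choices — the motivating figures do not state theirs — so
  profile shapes, not their absolute values, are the meaningful output.
* **Motif scanning** matches IUPAC consensi by bitmask comparison,
  reporting all overlapping hits on both strands (minus-strand hits at
  forward coordinates); non-ACGT sequence characters match only pattern
  `N`. Positional profiles deduplicate palindromic double reports by
  midpoint and pattern, and normalize per gene per bp of bin.
* **Expression integration** filters differential-expression tables at
  2-fold de-regulation (confidence filtering is the upstream caller's
  job), compares up-regulated fractions between peak-gene groups, and
  tests flat category→gene annotations with the exact hypergeometric
  tail plus BH. GO-DAG propagation is out of scope; the enrichment
  operation takes any flat annotation.

# Validation strategy and known limitations

Every statistical primitive is tested against an independent brute-force
oracle: binomial and hypergeometric tails against log-space
combinatorial summation ($|\Delta p| \le 10^{-12}$), BH against a
from-definition step-up (exact equality), window counts and interval
classifications against quadratic scans (exact), metagene bins against
per-base re-averaging ($10^{-12}$), the scanner against a naive
sliding-window matcher (exact). Pipeline-level behavior is validated on
the generator: ≥ 90% recall and ≥ 95% precision on fold-10 domains
(1 Mb, 30 domains, 2 × 10^5 reads per library), zero called peaks in ten
fold-1 null runs at the same scale, and recovery of the constructed
co-location rate (20 two-mark simulations, 200 domains each) within
binomial sampling error. These problem sizes are the package's validation
conditions; they keep the full suite to a few minutes on one CPU.

Two limitations deserve emphasis:

* **Candidate-level FDR is regime-dependent.** The
  threshold-then-test architecture preselects candidates by the same
  signal the binomial test measures. At high coverage (≥ 0.1 reads/bp)
  almost no null windows sustain 3-fold enrichment, so null candidates
  are rare, extreme fluctuations whose p-values are no longer marginally
  uniform — BH at a mild α would pass most of that tiny, selection-biased
  family. The overall caller remains silent under the null because the
  working cutoff $10^{-10}$ is far beyond what such fluctuations reach.
  At input-limited coverage (~0.01 reads/bp), where single-fragment
  windows cross the pseudocounted threshold and candidates are
  plentiful with near-uniform p-values, BH controls the false-candidate
  fraction as advertised; that is the regime in which the calibration
  test operates. Users applying mild q-cutoffs at high coverage should
  treat q-values as ranking scores, not literal FDRs.
* **Uniform-background realism.** Real input libraries have GC,
  accessibility and mappability structure that inflates local ratios;
  the simulations cannot detect sensitivity to such structure. The
  pseudocount and the input-matched binomial null mitigate but do not
  model it.

Smaller caveats: the gene-assignment rule of the motivating study is
unstated, so gene counts from real data are not comparable targets; the
exact motif consensi exist only as sequence logos, so the GAGA-repeat
default is configurable rather than hard-coded truth; and the treatment
control for the protein ChIP (its own input vs an untransformed-line
ChIP) is an analysis choice the caller leaves to the user — any control
BED is accepted.

# Worked example

```{r example, eval = FALSE}
library(prc2peaks)

cfg <- sim_config(seed = 1, n_chrom = 1, chrom_length = 1e6,
                  n_genes = 50, gene_length_range = c(2500, 5000),
                  n_truth_regions = 30, truth_fold = 10,
                  truth_length_range = c(1000, 2000),
                  reads_treatment = 2e5, reads_input = 2e5)
sim <- simulate_genome(cfg, with_sequence = FALSE)
truth <- simulate_truth_regions(cfg, sim$genes)
peaks <- call_peaks(simulate_reads(cfg, truth, "treatment"),
                    simulate_reads(cfg, truth, "input"),
                    sim$chrom_lengths, peak_call_config(L = 200))
truth_recovery(peaks, truth[truth$mark == "A"])
```

The numbered scripts under `analysis/` run the same machinery as a
complete narrative — simulation, two-mark peak calling, co-location and
gene assignment, metagene profiles, motif scanning, expression
integration — writing tables under `results/`.
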