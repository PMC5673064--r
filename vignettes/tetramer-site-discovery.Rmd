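---
title: "Discovering tetramer-specific binding sites by genotype-contrast ChIP-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering tetramer-specific binding sites by genotype-contrast ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrasite)
```

## The biological contrast

STAT5 can occupy DNA in two oligomeric states. Dimers bind single GAS
elements — the quasi-palindromic 9-mer `TTCYNRGAA`. Tetramers, formed by
N-domain contacts between two dimers, bind *pairs* of tandemly linked GAS
elements, often individually of lower affinity, separated by a short
spacer. A double-knockin (DKI) genotype with N-domain mutations retains
dimer binding but cannot tetramerise. ChIP-seq of WT cells therefore sees
dimer *and* tetramer sites; ChIP-seq of DKI cells sees dimer sites only.
The difference is the tetramer-specific cistrome, and genes that lose
both binding and cytokine-induced expression in DKI are nominated as
direct tetramer targets. `tetrasite` implements this workflow as
composable stages plus two composites, `run_discovery()` and
`run_integration()`.

## Peak calling

Reads are single-end; each read is shifted half a fragment length towards
its 3' end so that coverage is counted at estimated fragment midpoints
(`fragment_midpoints()`). Midpoints are tallied in non-overlapping 20-bp
windows and normalised to reads per million (`windowed_coverage()`).

A window with treatment count $k$ is candidate-enriched when the Poisson
upper tail $P(X \ge k \mid \lambda) \le p$ with $p = 10^{-5}$. The
background rate is estimated dynamically, as MACS-style callers do:

$$\lambda = \max\big(\lambda_\text{window},\ \lambda_\text{1kb},\
\lambda_\text{genome}\big),$$

the depth-scaled control count in the window itself, the control rate in
a surrounding 1-kb region, and the genome-wide expectation
$N w / G$ for library size $N$, window $w$ and effective genome size $G$
($2.7 \times 10^9$ by default for mouse-scale data; set it to the actual
genome length for toy genomes). Windows must also exceed $\lambda$
(enrichment > 1). Candidate windows separated by at most one window
merge into a peak; the summit is the centre of the maximum-count window,
leftmost on ties, which keeps the caller fully deterministic. The
contract here is "Poisson tail against a locally estimated background",
not bug-for-bug parity with any particular caller; duplicate reads are
retained because the simulator introduces none.

Two numerical anchors: with $\lambda = 2$, a window of 10 reads has tail
probability $4.6 \times 10^{-5}$ (not significant at $10^{-5}$) and a
window of 12 reads $1.36 \times 10^{-6}$ (significant). The tails agree
with direct pmf summation to $10^{-12}$ for counts up to 100 (tested).

Profile matrices take the 300 20-bp bins spanning $\pm 3$ kb around each
summit, filled with library-normalised counts, and are grouped with
`stats::kmeans` under a fixed seed (`kmeans_profiles()`, labels reported
0-based like all package coordinates).

## Motif geometry

`scan_gas()` matches the consensus (or a PWM, for relaxed
"non-consensus" matching) on both strands via Biostrings; windows
containing `N` never match. Because the degenerate consensus is its own
reverse complement, most elements match at the same interval on both
strands; hits are deduplicated by genomic interval so each physical
element counts once — spacing analysis counts *sites*, not
strand-stamped matches.

A tandem pair is any ordered pair of hits on one chromosome with

$$\text{spacer} = \text{start}_\text{down} - \text{end}_\text{up}
\in [0, \text{max\_spacer}],$$

i.e. the number of bases strictly *between* the two 9-mers. This
between-motif convention is fixed throughout (the generator records it in
the truth registry, the scanner reports it in every output) because it is
the only reading under which preferred spacings of 11–16 nt are
geometrically plausible for two adjacent GAS elements. Hit strands are
ignored: the element is quasi-palindromic and no strand rule is
biologically established. `max_spacer` defaults to 30 nt, comfortably
containing the preferred 11–13 and 16 nt spacings while excluding
unrelated neighbouring sites. `spacing_distribution()` histograms the
spacers, optionally restricted to pairs inside a peak set.

## Genotype contrast

`match_peaks()` pairs WT and DKI peaks one-to-one (interval overlap by
default; summit distance as an alternative for sharp peaks), resolving
candidates greedily by smallest summit distance with leftmost
tie-breaks — deterministic, and equal to the optimal assignment when
peaks are well separated. One-to-one matching is required because the
shared/specific accounting (`venn_accounting()`) must partition the peak
sets.

`classify_tetramer_sites()` computes, per WT peak, the
pseudocount-stabilised intensity ratio

$$r = \frac{\text{WT}_\text{rpm} + 0.5}{\text{DKI}_\text{rpm} + 0.5}$$

and classifies the site `tetramer_specific` when $r \ge$
`reduction_fold` (default 2), else `shared`. The source data show
reduction qualitatively, without a numeric criterion, so the twofold
default is this package's operationalisation; sites *absent* in DKI and
sites merely *reduced* stay distinguishable (`reduced` flag). Two
estimator choices matter and were made deliberately:

* For matched peaks, each genotype contributes its own summit height.
  Both estimates are then equally affected by summit-selection bias
  (the summit is an argmax over Poisson noise), so the ratio is unbiased
  near 1. Reading the DKI library at the WT summit instead would inflate
  $r$ at shared sites by roughly the selection bias and misclassify a
  few percent of dimer sites.
* Unmatched WT peaks are *not* automatically tetramer-specific: the DKI
  coverage at the WT summit stands in for the missing peak and the same
  ratio test applies. A site genuinely silent in DKI shows $r \gg 2$, so
  sensitivity is unaffected; but a WT peak that merely fragmented into
  two calls (its DKI counterpart matched to the other fragment) is
  correctly recognised as shared. Presence/absence of a near-threshold
  peak call is a noisy classifier; the intensity ratio is the robust
  statistic.

## Gene annotation and expression integration

A peak supports a gene when it overlaps, by at least 1 bp, the union of
the gene body and the strand-aware 5-kb upstream window — half-open
$[\text{tss}-5000, \text{tss})$ on the plus strand and the mirrored
interval on the minus strand, clipped at chromosome ends. Interval
overlap (not summit containment) is used; the boundary convention is
half-open everywhere, matching BED. `tetramer_genes()` collapses
tetramer-specific sites to unique genes, so the gene count is at most
the site count. Toy gene tables carry one TSS per gene; isoform
resolution is out of scope.

Expression uses RPKM,
$\text{rpkm} = 10^9 \cdot \text{count} / (\text{exon\_bp} \cdot
\text{library\_size})$, and purely threshold-based differential calls: a
gene passes a contrast when the larger RPKM of the pair is $\ge 5$ and
the fold change $\ge 1.5$ ($\ge 2$ for the IL-15 induction contrast).
**No p-values and no multiple-testing correction are computed anywhere**
— the DE definition is deterministic thresholding, and pretending
otherwise would misrepresent it. The "expressed in at least one
population" floor is applied per contrasted pair (the max of the two),
matching the per-transition framing of the analysis. Fold changes use an
RPKM pseudocount of 0.1 — small enough not to disturb genes above the
5-RPKM floor, large enough to stabilise ratios at zero. Replicate
handling is by condition grouping (means per population), since the
original design had single libraries per subpopulation.
`tetramer_targets()` intersects tetramer-bound genes with those
expressed $\ge 1.5$-fold higher in WT than DKI, preferring IL-15-treated
conditions when present.

## The synthetic study and what it does (not) show

The generator (`synthetic_config()`, `generate_genome()`,
`simulate_chip()`, `simulate_counts()`) defines the study conditions the
tests run under:

* **Genome**: 500 kb over two chromosomes, i.i.d. bases at GC 0.42,
  25 dimer + 25 tetramer sites. Sites sit $\ge 7$ kb apart and $\ge$ one
  fragment length from chromosome ends, so with 3-kb genes and the 5-kb
  upstream rule a planted site can only annotate to its host gene and
  peaks never merge across sites.
* **Libraries**: 25,000 background fragments per library — about one
  fragment midpoint per 20-bp window. This density was chosen by a
  false-positive budget: at $\lambda \approx 1$ per window the
  discreteness of the Poisson test leaves the per-window false rate near
  $10^{-6}$, i.e. ~0.03 expected false windows per genome, so "every
  peak sits on a planted site" is expected to hold run after run.
* **Enrichment**: active sites receive excess fragments at
  $(\text{enrichment\_fold}-1) \approx 19$ times the local background
  rate, midpoints uniform within half a fragment of the site centre.
  Tetramer sites are fully active in WT only; `residual_enrichment`
  (default 0) exposes the unknown in-vivo residual dimer occupancy at
  tetramer sites as a knob rather than asserting a value.
* **Spacers**: drawn from {11, 12, 13, 16} nt at 25% each, mirroring the
  preferred spacings; degenerate distributions are available for
  mode-recovery checks.
* **Counts**: negative-binomial with dispersion 0.01 and nominal 5e6
  mapped reads — tight, technical-replicate-like noise, appropriate
  because threshold-based DE without replicates presupposes
  low-variance libraries. Baselines are lognormal (median 20 RPKM), so a
  planted fourfold change is comfortably detectable while ~8% of genes
  sit below the 5-RPKM floor, exercising the filter.

Passing tests on these conditions show the *algorithms* are correct and
deterministic; they do not show robustness to what real data adds:
mappability structure, duplicate reads, GC and fragment-size biases,
copy-number variation, biological replicate variance, or overlapping
gene models. Absolute published counts (thousands of sites, hundreds of
genes) depend on the deposited libraries and exact aligner/caller
versions and are deliberately not simulation targets; the in-text *set
arithmetic* between those counts is reproduced exactly, and everything
else is validated as planted-truth recovery.

Problem sizes in the test-suite and acceptance runs (a 500-kb genome,
ten contrast seeds, a 600-gene DE experiment) are the package's chosen
desk-scale study; each full contrast takes well under a second of CPU.

## Numerical conventions and degenerate inputs

Coordinates are 0-based half-open everywhere internally and in BED
output; 1-based interchange happens only at the Biostrings boundary.
Summits tie leftmost; k-means runs under a caller-supplied seed with
`nstart = 5`; `k = 1` and `k = n` short-circuit to the exact answers.
Empty inputs return typed empty results (`find_tandem()` on one hit,
`spacing_distribution()` on no pairs, a tetramer-free genome) rather
than errors; genuinely unusable inputs (zero-depth libraries, mismatched
chromosome sets, missing populations, non-positive dispersion) fail with
named errors. Every generator is a pure function of its configuration
and seed, restoring the caller's RNG state.

## Known limitations

Single-end simulation only; no PCR duplicates or mappability model; the
caller has no broad-peak mode, no fragment-size estimation and no
FDR-by-swap; the contrast has no replicate-variance model (by design —
the upstream study had none); PWM matching is threshold-only, with no
motif discovery. These bounds mirror the scope of the workflow the
package re-implements.
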