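# tetrasite

Discovery of transcription-factor **tetramer-specific** genomic binding
sites by genotype-contrast ChIP-seq, with tandem GAS-motif spacing
analysis and expression integration.

## The problem

STAT5 binds DNA as a dimer at single GAS elements (the quasi-palindromic
9-mer `TTCYNRGAA`) and as a tetramer — two dimers joined through their
N-domains — at pairs of tandemly linked, often lower-affinity GAS
elements. A knockin mouse genotype (DKI) carrying N-domain mutations
forms dimers normally but cannot form tetramers. Comparing anti-STAT5
ChIP-seq of wild-type (WT, dimer + tetramer) against DKI (dimer only) NK
cells therefore isolates the *tetramer-specific* binding sites; genes
that both lose binding and lose expression in DKI are direct tetramer
targets. This package re-implements that computational workflow as a
tested, reusable pipeline, exercised end to end on synthetic genomes with
planted ground truth.

## What it computes

* **Peak calling** — a Poisson sliding-window caller: a 20-bp window with
  treatment count `k` is enriched when `P(X >= k | lambda) <= 1e-5`, with
  the background rate `lambda` the maximum of the depth-scaled control
  count in the window, the control rate in a surrounding 1 kb, and the
  genome-wide expectation `N * w / G` (effective genome size `G`, 2.7e9
  for mouse-scale data). Contiguous significant windows merge into peaks
  with summit, enrichment and reads-per-million height. Binned (+/-3 kb,
  20-bp) profile matrices around summits with k-means grouping.
* **Motif geometry** — GAS scanning on both strands (IUPAC consensus or
  PWM; palindromic self-matches deduplicated), enumeration of tandem
  pairs, and the spacer histogram, where the spacer is the number of
  bases strictly between the two 9-mers.
* **Genotype contrast** — one-to-one peak matching, WT/DKI intensity
  ratios with a 0.5 rpm pseudocount, classification into
  `tetramer_specific` (absent or >= 2-fold reduced in DKI) versus
  `shared`, and shared/specific Venn accounting.
* **Gene annotation** — the bound-gene rule: a peak supports a gene when
  it overlaps the strand-aware 5-kb-upstream window or the gene body.
* **Expression integration** — RPKM
  (`count * 1e9 / (exon_bp * library_size)`), threshold-based
  differential expression (RPKM >= 5 in at least one condition of the
  pair and fold change >= 1.5; >= 2 for cytokine induction) across the
  Q1 -> Q2 -> Q3 NK maturation transitions, and direct-target nomination:
  tetramer-bound genes with >= 1.5-fold lower expression in DKI.
* **Synthetic data** — genomes with planted single/tandem GAS sites,
  genotype-asymmetric ChIP libraries and negative-binomial count tables,
  all with full truth registries, so every stage is testable offline.

## Worked example

```r
library(tetrasite)

cfg <- synthetic_config(seed = 1)          # 500 kb, 25 dimer + 25 tetramer sites
res <- run_discovery(cfg, "out_demo")

res$venn
#> Venn counts: |A| = 50, |B| = 25, shared = 25
#>   A-specific = 25, B-specific = 0, union = 50
#>   shared fraction: 50.0% of A, 100.0% of B

res$spacing
#> Tandem GAS spacing distribution: 25 pair(s)
#>  spacer count
#>      11     8
#>      12     8
#>      13     4
#>      16     5
#> mode(s): 11, 12 nt

length(res$tetramer_genes)
#> [1] 25
```

Read: the WT library yields 50 peaks (A) and the DKI library 25 (B); the
25 DKI peaks all match WT peaks (the planted dimer sites), and the 25
WT-only peaks are the planted tetramer sites. Their tandem GAS pairs show
the planted spacer mixture over 11–16 nt, and each tetramer-specific site
annotates to its host gene. The same numbers are printed by the thin CLI
wrapper:

```sh
Rscript inst/scripts/tetrasite.R discover  --seed 1 --out out_demo
Rscript inst/scripts/tetrasite.R integrate --seed 1 --out out_demo_expr
```

Window-level arithmetic is exposed directly, e.g. the Poisson tail used
by the caller:

```r
poisson_tail(c(10, 12), lambda = 2)
#> [1] 4.649808e-05 1.364615e-06    # 10 reads miss the 1e-5 cut, 12 pass
```

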