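---
title: "Models and methods behind methylscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methylscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylscape)
library(dplyr)
```

# The problem

Whole-genome bisulfite sequencing (WGBS) reads report, at every
cytosine, how many aligned reads were protected from bisulfite
conversion (methylated, read as C) versus converted (unmethylated, read
as T). From those per-site pileups, a plant methylome analysis asks
four questions this package answers in order:

1. **Which cytosines are methylated?** Residual non-conversion means a
   small fraction $\varepsilon$ of truly unmethylated cytosines still
   reads as C, so a raw count is not a call.
2. **What does the methylation landscape look like** across contexts
   (CG, CHG, CHH), windows, chromosomes and gene regions?
3. **Which gene regions and windows changed** between a treatment and a
   control methylome sequenced without replicates?
4. **How does methylation change relate to expression change**, and to
   specific locus families such as miRNA precursors?

All containers are plain tables (tibbles), so every stage chains with
the pipe and is inspectable midway.

# Methylcytosine calling

At a site with $n$ reads of which $k$ are methylated, the call is a
one-sided exact binomial test of $k$ against the non-conversion rate:

$$p = P[X \ge k \mid X \sim \mathrm{Bin}(n, \varepsilon)]$$

$\varepsilon$ is estimated by pooling reads over a declared
unmethylated control set (`estimate_nonconversion()`), with a floor of
$10^{-4}$ so a perfectly converted control set cannot produce degenerate
p-values. P-values are adjusted with the Benjamini–Hochberg step-up
(written out in `benjamini_hochberg()`; the test suite cross-checks it
against both a from-definition implementation and `p.adjust`), and a
site is called methylated when $q \le 0.01$. The methylation level

$$\mathrm{ML} = \frac{mC}{mC + \text{non-}mC}$$

is reported for every tested site regardless of the call.

Three decisions here were genuinely open and are exposed as arguments:

* **Coverage floor** (`min_coverage`, default 4 reads): a standard
  stabilizer for ML; sites below it are excluded from testing entirely
  rather than tested and down-weighted.
* **BH family**: one family per condition across all contexts, matching
  a single stated genome-wide FDR; a per-context family would change
  borderline calls only.
* **Strand handling**: strands are sites in their own right (each has
  its own context read 5'→3' on its own strand) and are called
  separately; pooled-strand MLs are count-weighted combinations, which
  the suite asserts exactly.

# Landscapes

Windows, chromosome bins and gene metaprofiles all pool **read counts**,
never averages of site-level MLs: the pooled ML
$\sum mC / \sum(mC + \text{non-}mC)$ matches the ML definition and
naturally down-weights shallow sites. `sliding_window_levels()` tiles
from coordinate 0 at `width` 200 bp by default; because "sliding" is
ambiguous, `step < width` gives overlapping windows in which a site
contributes to every window containing it. Chromosome profiles use
10-kb bins with a centered moving average (default 5 bins, shrinking at
chromosome ends). Metaprofiles rescale each gene region to a fixed
number of bins oriented 5'→3' on the gene's own strand; regions made of
several intervals (a CDS split by an intron) are concatenated in
transcription order before binning.

Gene region models are built from GFF3 with 2000-bp upstream/downstream
flanks by default — the common plant-methylome convention, since flank
length is rarely stated in publications — truncated at chromosome
edges. Internally all intervals are 0-based half-open; readers and
writers convert from the 1-based closed conventions of GFF3 and
cytosine reports. A cytosine inside two overlapping genes contributes to
both genes' statistics independently.

# Differential methylation

Per gene × region × context, methylated-read counts are pooled and
normalized as RKTM — reads per kilobase of feature per million library
reads — where the library total is the condition's methylation-
supporting reads (an `"all"`-reads switch exists). The test is a
two-sided Fisher's exact test on the pooled
(methylated, unmethylated) counts of the two conditions; two-sided
because hyper- and hypomethylation are both of interest. BH runs across
every test in the run, and a feature is differentially methylated when
$q < 0.05$ **and** the RKTM ratio (either direction) exceeds 2.
Direction is `hyper` when the treatment ML exceeds the control ML.

A 0.5 pseudocount enters the RKTM **ratio** only when one side's count
is zero — never the Fisher table — so fold changes stay finite without
distorting the exact test. DMRs are the same test on aligned 200-bp
window tilings, with significant windows merged when adjacent (gap
`merge_gap`, default 0) and sharing context and direction. The
ratio can instead be computed on MLs (`ratio_mode = "ml"`) since
published level-based filters exist; RKTM is the default.

# Expression integration

With one library per condition, `de_test()` implements the
Audic–Claverie exact test: the second library's count, given the
first's, follows a negative binomial
$\mathrm{NB}(k_a + 1,\ N_a/(N_a+N_b))$, and the two-sided p is twice
the smaller tail. This classic form conditions on one count, so it is
not perfectly invariant under swapping the libraries; the
`method = "conditional"` variant (exact conditional binomial on the
count total) is exactly swap-symmetric and agrees closely at moderate
counts. The default follows the classic form; the choice is pluggable
because the underlying no-replicate algorithm in the motivating study
design is unnamed, and Audic–Claverie was the standard method of that
era for BGI-style pipelines.

`call_de()` flags genes at FDR $\le 0.001$ and $|\log_2\mathrm{FC}| \ge
1$, with log2FC computed on library-size-normalized counts plus a
pseudocount of 1. The **joint filter** deliberately uses the *raw*
methylation p-value ($p < 0.05$, fold $\ge 2$) rather than the DMG
caller's FDR — the two thresholds answer different questions and both
significance columns are carried through. `association_summary()`
reports, per region (and optionally per gene class), the Spearman
correlation between methylation log2 ratio and expression log2FC plus
quadrant counts.

# miRNA precursor loci

`locus_methylation()` pools all covered cytosines in a precursor
interval — both strands, all contexts — into one ML per condition,
because published locus tables report a single level per locus. The
change statistic is $\log_2(\mathrm{ML}_t/\mathrm{ML}_c)$, and the
two-fold filter keeps $|\log_2| \ge 1$. Full precision is kept
internally; tables round to 2 decimals at reporting only.

The bundled reference table (`mirna_reference_table()`) contains the
published per-locus ML pairs for 15 rice miRNA loci under atrazine
exposure. Ten rows are arithmetically self-consistent and the package
reproduces their printed log2 values to ±0.01; five rows print the raw
ML ratio in the log2 column (e.g. 0.45/0.21 printed as 2.14). Those
rows are flagged `consistent = FALSE` and left exactly as published —
the discrepancy is reported, not silently corrected.

# The simulator

`simulate_methylation_experiment()` generates the full study: genome,
annotation, truth methylomes, bisulfite pileups and coupled expression.
Its defaults are fixed study conditions, not tuning knobs:

| Parameter | Default | Why |
|---|---|---|
| GC content | 0.43 | rice-like euchromatin |
| Beta level means (CG/CHG/CHH) | 0.60 / 0.35 / 0.10 | plant context hierarchy |
| Methylated fractions | 0.50 / 0.40 / 0.10 | reproduces ~CG-majority mC composition |
| Beta concentration | 10 | broad but unimodal site levels |
| Non-conversion $\varepsilon$ | 0.004 | conversion ≈ 99.6% |
| Mean depth / strand | 20× (Poisson) | typical plant WGBS; fixed-depth switch for tests |
| Treatment effect | ±0.4 level shift | a stand-in: no quantitative effect-size distribution is published for this design, so the preset is labelled as such |
| Expression coupling | upstream-hyper → log2FC −1; genebody-hypo → +1; noise sd 0.25 | encodes the reported direction of association |

Depth is Poisson rather than fixed so low-coverage handling is
exercised. All randomness flows from one master seed through
per-component substreams, making fixtures byte-reproducible.

**Desk-scale problem sizes.** The test and acceptance simulations use
1-kb gene bodies, 1-kb flanks and 2.2-kb intergenic gaps (so flanks
never overlap neighboring gene bodies), with 30–1000 genes on 0.1–3.3 Mb
of genome. The flank size follows a power computation, not convenience:
an upstream region with $n_{CG}$ cytosines has a baseline pooled-ML
standard deviation of roughly $0.32/\sqrt{n_{CG}}$ across genes under
the preset, and a gene only clears the strict two-fold filter after a
+0.4 shift when its baseline is below ≈0.36. At 1-kb flanks
($n_{CG} \approx 90$) the baseline spread leaves ~95% of shifted genes
above threshold; at much shorter flanks the fixture, not the method,
caps recall. With the full 2-kb default flank on a real genome the
effect is stronger still.

**What the simulator does not emulate:** sequence composition bias
(i.i.d. bases, no repeats or TE families), spatially correlated
methylation, replicate structure (one pooled library per condition by
design), mapping artefacts, and read-level error profiles beyond a
single symmetric rate. Passing tests therefore demonstrate statistical
correctness of the pipeline under its stated model, not robustness to
alignment or repeat-driven artefacts in real libraries.

# Numerical notes

* Fisher p-values from `fisher.test` are clamped at 1 (floating-point
  overshoot on symmetric tables).
* Sites whose two-base context window contains `N` or runs off the
  chromosome end are excluded everywhere rather than given a fallback
  context.
* Sites with zero coverage are excluded from testing, never assigned
  $p = 1$; windows and loci with no covered sites report `NA`.
* A zero margin in a 2×2 table returns $p = 1$ by convention.
* The analysis stages use no RNG; `run_pipeline()` on fixed inputs is
  byte-deterministic, which the suite asserts by rerunning and
  comparing files.

# A worked micro-example

```{r example, eval = FALSE}
exp <- simulate_methylation_experiment(chrom_len = 1e5, n_genes = 30,
                                       n_effect = 5, seed = 1)
calls <- call_methylome(exp$pileups, epsilon = 0.004)
glance(calls)
diff <- call_differential_features(
  feature_methylation(calls, exp$gene_models))
glance(diff)
summarize_dmgs(diff)
```

# Known limitations

* No beta-binomial overdispersion: pooled libraries hide biological
  replicate variance, so p-values are anti-conservative for noisy real
  data — exactly as in the no-replicate designs this reproduces.
* No smoothing-based DMR calling (BSmooth-style); DMRs are merged
  significant windows.
* Repeat/transposon annotation is taken from the supplied GFF3 as
  ordinary features; nothing is inferred from sequence.
* GO/KEGG enrichment and miRNA target prediction are out of scope.
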