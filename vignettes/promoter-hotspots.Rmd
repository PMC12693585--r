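---
title: "Scoring promoter evolution hotspots and their expression consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring promoter evolution hotspots and their expression consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promevol)
```

## The problem

Seminal fluid proteins, most of them accessory gland proteins (Acps) in
*Drosophila*, evolve fast on average, yet only a minority show adaptive
coding-sequence evolution. One candidate driver of their rapid divergence is
the promoter: if Acp promoters accumulate base changes and indels faster
than those of comparable genes, regulatory change rather than protein change
could explain the rapid expression divergence seen between closely related
species — and hybrid accessory glands, which develop normally, let one ask
whether species-specific expression is carried by the allele (*cis*) or by
the cellular environment (*trans*).

promevol implements that analysis as a reusable pipeline over five stages:
tissue-specific gene-set selection, CAGE-based dominant-TSS calling, event
coding of multi-species promoter alignments, two families of hotspot scores
(sliding-window and positional), and an expression-divergence layer for
species and hybrid-allele comparisons. A synthetic-data generator emulates
every external input with known truth so the whole pipeline is testable
offline. The interface is the exported R functions (driven from scripts or
interactively); no shell wrapper is shipped.

## Gene sets: the tissue-specificity index tau

For a gene's expression profile $x_1 \dots x_N$ over $N$ tissues,

$$\tau = \frac{\sum_{i=1}^{N} (1 - x_i / x_{\max})}{N - 1},$$

so $\tau = 0$ for uniform expression and $\tau = 1$ for single-tissue
expression. `tau()` works on untransformed values by default; a
`log_transform` flag applies $\log_2(x+1)$ first, since published uses of
the index vary on this point. An all-zero profile has no defined $\tau$ and
returns `NA`, never 0.

Because $\tau$ alone does not say *which* tissue dominates,
`select_gene_set()` requires both $\tau \ge 0.9$ (the conventional
tissue-specificity threshold) and the row maximum in the target tissue.
`top_specific_genes()` adds ranking by $\tau$ with ties broken by gene
identifier, for size-matched controls such as a top-50 Malpighian-tubule
set, and `random_control_sample()` draws the seeded random genome sample
used as the main control group.

## Dominant TSS from CAGE

Genes with several annotated TSSs are represented by the candidate with the
highest nine-nucleotide CAGE window score
(`cage_window_score()`): the sum of per-base CAGE signal in a window
centered on the candidate. Centering is symmetric with respect to CAGE peak
position inaccuracy, which is the reason the window exists; windows are
truncated (not discarded) at track ends so boundary candidates remain
scoreable. Exact ties go to the 5'-most candidate on the gene's strand —
deterministic, and favouring the annotated primary start. Only annotated
candidates are ranked; de novo peak calling is out of scope.

## Event coding of promoter alignments

All comparisons are one species against a designated reference row, on the
window of reference offsets $[-1000, +300)$ around the TSS
(`trim_to_window()`; offsets count reference bases, alignment columns
gapped in the reference are kept between retained columns). Coordinates are
0-based half-open on disk (BED/bedGraph) and signed TSS offsets internally,
with minus-strand tracks reversed so offsets always increase downstream.

`pairwise_events()` codes each reference base 0 (conserved) or 1 (changed)
in three modes: `base` (nucleotide mismatch; `N` and soft-masked input count
as conserved to avoid scoring assembly artifacts), `indel`, and `all` (their
OR). Deletions mark every affected reference base — the per-nucleotide
coding the sliding scores need — while insertions have no reference base of
their own and collapse to a single 1 at the reference base immediately 5' of
the block. An insertion before the first reference base has no anchor and is
dropped with a warning. Columns gapped in both rows are skipped entirely.

For the positional analysis, `event_positions_5prime()` instead collapses
each contiguous indel to one event at its 5' start (the convention for
positioning indels in an alignment) and reports alignment columns, since
positional clustering is defined on the alignment, not on reference offsets.
Whether multi-base deletions should count once or per base in the *tallies*
has no single established convention; the per-base coding is the default
(each nucleotide is assigned a value), and the collapsed list feeds only
the G-function stage.

## Sliding event scores, d, and d^P

`sliding_event_score()` sums events in a 5-base centered window (truncated
at the ends) over a single pair or a multi-pair/multi-gene tally. The
control baseline $Se^C$ (`control_baseline()`) is the *global* mean of all
control Se values over the scored region — a single scalar, matching its use
as one average score rather than a per-offset profile.

The hotspot score $d$ (`d_score()`) is the percentage of events in a 350-nt
promoter region whose Se strictly exceeds $Se^C$. The default region is
offsets $[-380, -31]$: 350 nucleotides upstream of a TATA box estimated at
offset $-30$, the canonical core-promoter placement; TATA positions vary by
gene, so the region is a parameter. With
the numerator counting *events*, $d \in [0, 100]$ by construction; the
alternative reading (all region positions above baseline over the same
denominator) is available as `d_mode = "positions"` but can exceed 100. A
region with no events is flagged (`status = "no_events"`) rather than
silently scored 0. The PhyloP analogue $d^P$ (`phylop_d_score()`) counts
region positions with conservation strictly *below* the control mean $p^C$;
missing values are excluded from both counts with a warning.

Group comparisons use the field-standard tests: unpaired two-sided
Student t-tests for metagene conservation means, Pearson 2×2 chi-squared
without continuity correction for $d$/$d^P$ fractions with Bonferroni
correction across that family, and Benjamini–Hochberg FDR for the
expression-fraction family (`divergence_fraction()`).

## Positional hotspots: the G function

For $n$ collapsed events at sorted alignment columns $x_1 < \dots < x_n$ in
an alignment of $L$ columns,

$$G_k = \frac{k}{n} - \frac{x_k}{L},$$

the difference between the relative occurrence of a change and its relative
position. Uniformly spread events keep $G$ flat; a run of tightly packed
events produces a climb. The test statistic is the maximal climb
$\max_{i<j} (G_j - G_i)$ (`max_stretch()`, ties to the smaller $i$ then
$j$); testing each consecutive $\Delta G$ alone is the other defensible
statistic, and is available by inspecting `delta_g` directly, but the
maximal climb is the default because it targets the object of interest — a
*stretch* of substitutions.

The null is Monte Carlo: `monte_carlo_null()` draws $n$ distinct columns
uniformly (sampling sites without replacement), 100,000 resamples by
default, with the hot loop in compiled code driven by R's RNG for
reproducibility. The empirical p-value uses the $(1+b)/(1+B)$ estimator and
is therefore never exactly 0. `call_hotspots()` masks a significant stretch
and retests the remaining events against a null re-simulated at the reduced
$n$, so multiple hotspots per alignment are recovered iteratively. Events
from all non-reference species are pooled per alignment by default
(per-species analyses simply pass one species' events).

## Expression divergence and hybrid alleles

`tpm()` uses plain length-in-kb normalisation (no effective-length
correction); columns sum to $10^6$ by construction. `log2fc()` compares
group means with a default pseudocount of 1 TPM, a conventional
stabiliser. Two
significance rules are used downstream: $|\log_2 FC| \ge 0.5$ with adjusted
$P \le 0.05$ (both boundaries inclusive, `classify_de()`), and the strict
$|\log_2 FC| > 1$ rule inside `tertile_enrichment()`, which bins genes by
$d$ into $(0,33]$, $(33,66]$, $(66,100]$ with $d=0$ in the first bin.
Moderated differential-expression models are deliberately *not*
re-implemented: adjusted p-values are consumed from upstream tables, because
the pipeline's contribution is the downstream fraction and enrichment
statistics, not the model fit.

Hybrid tables carry two allele rows per gene. `hybrid_allele_filter()`
removes excluded chromosomes (the X is inherited from a single parent in
these hybrids, so X-linked genes are mono-allelic by construction) and genes
expressed in fewer than 4 of the pooled allele × replicate columns; pooled
counting was chosen over per-sample counting as the stricter reading of the
filter, and both the threshold and the chromosome set are parameters.
`densitometry_log2fc()` reproduces the gel quantification: band intensity is
divided by fragment length (per-nucleotide stain signal is what is
comparable between digested and undigested products), summed per allele, and
log2-ratioed. `hybrid_vs_nonhybrid_ratio()` normalises hybrid-allele to
non-hybrid fold changes; a value near 1 means the species difference is
maintained in *cis*, and it is undefined (an error, not ±Inf) when the
non-hybrid change is 0.

## The synthetic generator

`simulate_dataset()` emulates the external inputs: FlyAtlas2-like tissue
matrices, UCSC-style conservation and CAGE bedGraphs, TSS BEDs, and
GEO-style species and hybrid count tables, with truth files for every stage.
Key defaults: uniform-ACGT reference over the 1300-base window; per-site
substitution rate 0.05 and indel initiation rate 0.01 at divergence 1
(promoter-scale divergence between close relatives), geometric indel lengths
with mean 3; a divergence ladder of 0.4/0.5/1.0/1.2 for the four
non-reference species, qualitatively echoing the melanogaster subgroup; a
5× rate multiplier inside the scored region $[-380, -31]$ for hotspot
genes; conservation N(1.5, 0.5) depressed by 2 at event positions; CAGE
peaks of height 20–100 with the dominant candidate scaled 5×; negative
binomial counts with mean 200 and dispersion 0.1, three replicates, true
log2 fold changes N(0, 1); 20% X-labelled genes, absent from the reference
allele in hybrids.

Events are generated directly on the reference frame and the alignment
emitted with explicit gaps, so the generator's bookkeeping is an *exact*
oracle for the event-coding stage. That is a deliberate idealisation: real
promoter alignments carry aligner ambiguity, so passing the recovery tests
demonstrates correctness of the coding and scoring logic, not robustness to
misalignment, repeat-induced gap placement, unannotated TSSs, or
normalisation artifacts in real count data.

## Numerical choices and degenerate inputs

Strict inequalities for $Se > Se^C$ and $p < p^C$; inclusive boundaries for
the 0.5/0.05 significance rule; strict for the $|\log_2 FC| > 1$ rule — each
deliberate and tested at its boundary. Empirical p-values never reach 0. All-zero tau profiles, empty
candidate lists, all-zero samples in `tpm()`, zero densitometry signals,
zero non-hybrid fold changes, and overlapping bedGraph records are errors or
flagged missing values, never silent zeros. Windowed sums are truncated at
boundaries everywhere (CAGE f, Se). bedGraph writing merges equal-value
runs and round-trips values exactly; conservation tracks are rounded to 4
decimals at generation time for that reason.

## Problem sizes used in the checks

The shipped verification suite runs the oracle comparisons at 1000 random
instances each; Monte Carlo calibration at $n = 25$, $L = 1300$, 2000
resamples, 500 null replicates (the any-hotspot rate must sit inside the
99% binomial interval around $\alpha = 0.05$); planted-cluster recovery (10
events in a 20-column window among 25 total) over 200 replicates; and
expression recovery at 300 genes × 3 replicates. These sizes give stable
pass/fail behaviour for the properties being asserted while keeping a full
run in the low minutes; production analyses would use the 100,000-resample
default for the null.

## Known limitations

Alignment computation, read processing and moderated DE fitting are out of
scope by design; pre-aligned FASTA and count/log2FC tables are inputs. The
TATA-box position is estimated, not inferred per gene. The G-function
analysis assumes events at distinct columns (merge co-located events
first). Genome-scale gene lists and percentages require the external
expression atlases, conservation tracks and RNA-seq datasets themselves and
are not attempted here; the synthetic suite verifies the machinery, and
group-level contrasts
(hotspot-planted vs control genes) recover the expected direction and
significance under the implemented tests.
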