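---
title: "Methods: models, statistics and design choices in tadscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, statistics and design choices in tadscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadscape)
```

## Scope

tadscape implements an integrative analysis of how partial depletion of
linker histone H1 (as in triple-knock-out, "TKO", embryonic stem cells with
roughly half the normal H1-to-nucleosome stoichiometry) reshapes the
regulatory genome, at four levels:

1. **DNA methylation** from paired methylation-sensitive (HpaII) and
   methylation-insensitive (MspI) restriction counts per CCGG site.
2. **Open chromatin and histone marks** from replicated region-level count
   tables (DNase hypersensitivity, H3K4me1, H3K4me3, H3K27me3, H3K9me3).
3. **TAD-level enrichment**: where in the genome the changes concentrate,
   using topologically associating domains (TADs) as the unit of analysis.
4. **Hi-C topology**: A/B compartments, contact distance decay,
   paired-anchor aggregation (PE-SCAN) and the per-TAD domain score.

Upstream processing (alignment, peak calling, chromatin-state segmentation,
TAD boundary calling, RNA-seq differential expression) is out of scope;
those products are consumed as inputs. Because the corresponding raw data
are not required, the package ships a synthetic generator that emulates the
signal structure of such an experiment with *planted*, parameterized
effects, so every estimator can be validated by parameter recovery.

## Methylation model and test

The methylation score maps normalized HpaII/MspI counts onto a 0-100 scale
via the angle transform

$$ s = 100\left(1 - \tfrac{2}{\pi}\,\mathrm{atan2}(h_n, m_n)\right), $$

where $h_n$ and $m_n$ are the depth-normalized HpaII and MspI counts.
HpaII cuts only unmethylated sites, so the score decreases monotonically in
HpaII signal: no HpaII signal means a fully methylated site (score 100),
HpaII signal without MspI signal scores 0, equal normalized counts score
50. This is a stated, monotone angle-based scoring; the exact confidence
weighting used by the original assay software is not reproduced. Each
digest library is normalized by its own total, so the average assayable
site sits near the middle of the scale.

Differential methylation is tested per site with an exact binomial test,
conditional on the total HpaII count across conditions: under the null the
TKO HpaII count is $\mathrm{Bin}(n, p_0)$ with $p_0$ the TKO share of
sequencing depth. The two-sided p-value is defined as
$\min(1, 2\min(\text{lower tail}, \text{upper tail}))$ — simple and
verifiable against direct tail summation (the test suite checks agreement
to 1e-12). Sites are called at $p < 10^{-6}$; the *stringent* set further
requires an absolute score change of at least `delta_threshold` (default
25 score units; the threshold is a configuration value since only "more
stringent criteria" is specified by the analysis this reimplements).
Conditioning on depth factors rather than raw totals is our choice.

Spatial clustering of differential sites is assessed by tiling each
chromosome with fixed non-overlapping windows (default 20 kb) anchored at
coordinate 0 (last partial window kept), counting windows holding at least
`min_sites` (default 5) differential sites, and comparing against draws of
equally many sites sampled uniformly without replacement from the
assayable set (default 1000 draws), with the add-one empirical p-value
$(1 + \#\{\text{null} \ge \text{obs}\})/(\text{draws}+1)$. The assayable
set is put in canonical genomic order before drawing, so the result does
not depend on input row order.

Chromatin-state composition assigns each site the state at its interval
midpoint (sites are tens of bp; midpoint assignment avoids double
counting) and reports a size-matched random draw from the assayable set as
baseline.

## Region-level count testing

All DNase/ChIP tests run on a shared region universe with per-replicate
counts. Library size factors are totals over their geometric mean. The
differential test pools replicates per condition and, conditional on the
pooled total, tests the TKO share against the size-factor expectation —
an exact conditional Poisson (binomial) test. The published analysis used
PoissonSeq for DNase and diffReps for ChIP windows; those tools are *not*
re-implemented verbatim. A single oracle-verifiable conditional test
replaces both, keeping the cited thresholds as mode defaults: a 5%
Benjamini-Hochberg FDR for DNase, raw $p < 0.001$ for ChIP windows.
Replicate-aware dispersion estimation (negative-binomial GLMs) is a
deliberate non-goal; the synthetic counts are Poisson, matching the test's
assumptions, and the type-I error of the test is checked by simulation.

The log2 fold change uses size-factor-normalized pooled counts with a 0.5
pseudocount to stay finite at zero.

De novo DNase hypersensitive sites are regions called only in TKO whose WT
H3K4me1 *and* H3K4me3 signal falls below the 25th percentile of WT
called-peak signal (no threshold value is published; the quantile is
exposed as `wt_quantile`). De novo H3K4me1 sites are defined analogously
with H3K4me3 and DHS as the WT filters. Overlap significance between
changed-site sets uses an upper-tail hypergeometric test with membership
defined by at least 1 bp of overlap with universe regions.

## TAD enrichment

Sites are assigned to the TAD containing their midpoint; genes are
assigned by transcription start site (TSS), the regulatory anchor (a gene
body may straddle a boundary; an overlap-based mode is available through
the site-assignment path by passing gene bodies instead of TSS points).
Sites in inter-TAD gaps are excluded from percentages but reported, so
totals stay auditable. TADs are ranked ascending by a key and split into
five equal-count bins (remainder distributed from the lowest bin upward;
ties broken by genomic order), with bin 1 the lowest 20%. Per-bin
percentages, enrichment ratios against a reference distribution, and a
4-df Pearson chi-squared test against reference proportions complete the
toolkit; the chi-squared refuses totals below 25 or non-positive expected
counts and recommends an exact test instead. Promoter-proximal changes
count a gene when any changed site midpoint lies within
$[\mathrm{TSS}-2500, \mathrm{TSS}+2500)$ bp.

## Hi-C topology

Contacts are binned at 100 kb. Balancing uses symmetric iterative
proportional fitting (Sinkhorn) after masking bins whose row sum is below
10% of the median positive row sum, iterating until all unmasked row sums
are within tolerance of their mean; the normalization used by the original
study is under-specified, so this modern, convergence-testable standard
was chosen. Compartments come from the first eigenvector of the Pearson
correlation matrix of the observed/expected matrix, computed per
chromosome (no genome-wide stitching), with the sign oriented so that the
eigenvector correlates positively with gene density (A = positive).
PE-SCAN averages the observed/expected windows around all eligible anchor
pairs (default flank 5 bins, pair distances 2-50 Mb to avoid diagonal
dominance) and summarizes the center cell over the border mean.

The domain score of a TAD is its intra-domain contact sum (upper triangle
including the diagonal, over bins fully inside the TAD) divided by its
cis cross-boundary sum, with a pseudocount of 1 on both terms so fully
insulated TADs stay finite; whether the original computed it on raw or
balanced matrices is unstated, so balanced is the default with raw
available. WT/TKO comparison uses the two-sample Wilcoxon rank-sum test on
the score distributions plus per-TAD deltas; ranking TADs by delta and
tabulating each mark's changes per quintile (with the chi-squared test
above) quantifies whether topological weakening concentrates where the
epigenome changed, alongside negative-control rankings by gene count, TAD
size and DE-gene count.

## The synthetic generator

`sim_params()` fixes the study conditions; `make_genome()` and the four
`simulate_*()` functions derive everything else deterministically from one
root seed via fixed-offset streams (adding a simulator never perturbs
another's draws).

Default scale: 2 chromosomes x 25 Mb, 100-kb bins, 200 TADs (each at
least two bins, with occasional inter-TAD gap bins and mild size
variation), 2000 genes, 50,000 methylation sites, 5000 signal regions,
5e5 contacts per chromosome matrix. This is large enough for stable
quintile statistics while keeping the full test suite in minutes on one
CPU. A 20-Mb chromosome would leave exactly two bins per TAD with no gaps
at all, so 25 Mb was chosen to keep the gap-handling and TAD-size code
paths exercised.

Key planted effects and their defaults:

* **Gene-density gradient** across TAD quintiles: geometric weights
  $g^{(q-1)/4}$ with $g = 12$, so the top:bottom quintile gene-count ratio
  equals $g$ by construction (the observed gene share of the richest
  quintile is then ~50% and the poorest ~4%, matching the reported
  pattern). Gene-dense TADs preferentially occupy the A compartment.
* **Methylation**: 1.5% of sites are differential, hypo:hyper 14:1 (the
  93%/7% stringent asymmetry). DMR placement is skewed toward gene-dense
  TADs with top:bottom rate ratio `dmr_gene_density_skew` (default 4).
  Counts are Poisson around site-level gamma factors shared between
  conditions — marginally negative binomial (overdispersed), while
  preserving the conditional binomial null; an independent-NB model would
  invalidate *any* conditional count test, not just ours. The planted
  shift of 0.7 on the latent methylated fraction corresponds to roughly
  50 score units through the angle transform (which compresses changes at
  the scale ends). Reference depth 250x reflects the deep-coverage regime
  of a targeted restriction assay.
* **Signal regions**: non-overlapping 500-bp regions (a merged peak
  universe) placed with the gene-density weights. DHS gains (2.4%) are
  off-to-on events with planted log2 fold change 2; with probability 0.3 a
  DHS gain also gains H3K4me1 at the same region; 30% of DHS gains are
  "bookmarked" (strong WT H3K4me1/me3, hence not de novo). H3K4me1 losses
  skew toward gene-poor TADs; repressive-mark changes are ~2% of the
  active-mark rates (essentially negligible, as observed).
* **Hi-C**: expected contacts decay as $d^{-1}$; same-compartment pairs
  are scaled by $1 \pm 0.5$, within-TAD pairs by $2$; in TKO, the
  cross-boundary contacts of "altered" TADs (20% of TADs, drawn
  preferentially from gene-dense quintiles, which also attract extra
  planted epigenetic changes) are inflated by 1.3, lowering their domain
  score. Counts are Poisson around the expectation, symmetric by
  construction.
* **DE genes**: 3% of genes, drawn uniformly (a proportional, apparently
  random collection with respect to TAD structure), 77% down-regulated.

No generative distributions are published for any of these assays; all
count models above are implementer choices and are flagged as such here.

### What the generator does *not* emulate

Read-level artifacts (mappability, GC bias, duplicates), genome sequence
content and CpG density, overlapping or nested peaks, trans-chromosomal
Hi-C structure, replicate-level batch effects beyond lognormal depth
variation, and sub-TAD clustering of DMRs beyond the TAD-quintile skew
(so the 20-kb window clustering test is only weakly loaded at the default
parameters). Passing recovery tests therefore demonstrates correctness of
the estimators under the stated models, not robustness to every artifact
of real sequencing data.

## Numerical choices

* Two-sided exact p-values: doubled smaller tail, capped at 1.
* Binomial/hypergeometric tails via `pbinom`/`phyper`; BH via `p.adjust`;
  Wilcoxon via `wilcox.test` with the normal approximation (tied scores
  are possible after balancing).
* Balancing tolerance 1e-6 on relative row sums, 200 iterations maximum,
  with a hard error (reporting the residual) on non-convergence.
* Quintile ties broken by genomic order (stable sort), keeping results
  deterministic.
* Empty-input sentinels rather than errors where a result is legitimately
  empty (no jointly significant regions, no eligible anchor pairs); hard
  errors for malformed input (zero-total libraries, empty site lists,
  TADs below two bins are skipped with a warning).
* All file coordinates are 0-based half-open; the COO format stores the
  upper triangle only, and duplicate cells merge by summation with a
  warning on read.

## Known limitations

The conditional count test ignores replicate-level overdispersion; with
strongly overdispersed real replicates its p-values would be
anti-conservative (a negative-binomial GLM would be the upgrade path).
The angle-based methylation score is a monotone stand-in, not the original
assay's exact scoring. Compartment eigenvectors are per-chromosome and
sign-oriented by gene density only. The domain-score comparison treats
TADs as independent, as does the published Wilcoxon analysis.
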