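# tadscape

Integrative analysis of how depletion of linker histone H1 reshapes the
epigenome and the 3D genome of embryonic stem cells. H1 triple-knock-out
("TKO") ES cells carry roughly half the normal H1-to-nucleosome
stoichiometry; comparing them with wild-type cells requires combining four
layers of evidence, and this package implements the statistics for each:

* **Differential DNA methylation** from HpaII/MspI restriction counts:
  an angle-based methylation score
  `s = 100·(1 − (2/π)·atan2(h_n, m_n))` on normalized counts, an exact
  conditional binomial test per CCGG site (`p < 1e-6`), a stringent-call
  class adding a minimum score change, a window permutation test for
  spatial clustering (20-kb tiles, ≥5 sites, 1000 null draws), and
  chromatin-state composition profiles.
* **Differential DNase/ChIP signal** over a region universe: library size
  factors, a pooled exact conditional count test, Benjamini–Hochberg FDR
  (5%) for DNase or raw-p (0.001) calling for ChIP windows, de novo
  DHS/H3K4me1 definitions (TKO-only calls lacking threshold WT
  active-mark signal), hypergeometric overlap tests and cross-mark
  concordance.
* **TAD-level enrichment**: midpoint assignment of sites to topologically
  associating domains, quintile binning by any ranking key, per-bin
  percentages and enrichment ratios, chi-squared non-uniformity tests,
  and TSS-proximal change percentages (±2500 bp).
* **Hi-C topology**: contact binning (100 kb), Sinkhorn balancing, A/B
  compartment eigenvectors from the observed/expected correlation matrix,
  distance-decay curves and exponent fits, PE-SCAN paired-anchor
  aggregation, and the per-TAD **domain score** — intra-domain contacts
  over cis cross-boundary contacts — with a Wilcoxon rank-sum WT/TKO
  comparison and delta-score quintile analyses.

A first-class synthetic generator (`sim_params()`, `make_genome()`,
`simulate_methylation()`, `simulate_signal_regions()`, `simulate_hic()`,
`simulate_de_genes()`) plants every effect with known truth — gene-density
gradients across TADs, a 14:1 hypo:hyper methylation asymmetry, concordant
multi-mark gains at new DHSs, distance-decaying TAD-blocked
compartmentalized contact maps, and a TKO-specific domain-score reduction
in epigenetically altered TADs — so each estimator is validated by
parameter recovery.

## Worked example

```r
library(tadscape)

params <- sim_params(seed = 1)           # the default study conditions
genome <- make_genome(params)
meth   <- simulate_methylation(genome)

md <- meth_diff(meth)                    # scores, binomial test, stringent set
table(md$direction)
#>  hyper   hypo   none
#>     49    700  49251

round(100 * sum(md$stringent & md$direction == "hypo") /
        sum(md$stringent), 1)
#> [1] 93.4                               # hypo share of stringent DMRs

bins <- quintile_bins(genome$tads$gene_count)
dmr  <- assign_sites_to_tads(md[md$direction != "none", ], genome$tads)$counts
all  <- assign_sites_to_tads(md, genome$tads)$counts
round(enrichment_ratio(bin_percentages(dmr, bins)$pct,
                       bin_percentages(all, bins)$pct), 2)
#> [1] 0.57 0.51 0.87 1.16 1.82           # DMRs enriched in gene-dense TADs
```

The last line reads: relative to where assayable sites sit, differential
methylation is depleted from the gene-poorest TAD quintile (ratio ≈ 0.6)
and enriched in the gene-richest (ratio ≈ 1.8). The full pipeline —
simulation, all four analysis stages, and fixture/result files — runs as

```r
report <- run_pipeline(run_config(seed = 1), outdir = "out")
report$hic$comparison$p        # Wilcoxon p for the TKO domain-score shift
```

or from a shell via the thin wrapper `inst/scripts/tadscape.R`
(`simulate` / `run` subcommands, `--seed`, `--config run.yaml`).

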