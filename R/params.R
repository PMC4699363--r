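#' Simulation parameters for the synthetic two-condition dataset
#'
#' Bundles every knob of the synthetic-data generator with validated
#' defaults. The defaults encode the study conditions the generator
#' emulates: a strong gene-density gradient across TADs, a heavy excess of
#' hypomethylation over hypermethylation after histone H1 depletion
#' (roughly 14:1 among stringent calls), a few percent of regulatory
#' regions gaining or losing DNase hypersensitivity, frequent co-gain of
#' H3K4me1 at new DHSs, essentially unchanged repressive marks, and Hi-C
#' maps with power-law distance decay, A/B compartment blocks, TAD
#' insulation, and a TKO-specific inflation of cross-boundary contacts in
#' epigenetically altered TADs.
#'
#' @param seed integer root seed; every sub-simulator derives its own
#'   fixed-offset stream from it, so identical params give bit-identical
#'   output.
#' @param n_chrom,chrom_length genome model: number of chromosomes and the
#'   (equal) length of each in bp; must be a multiple of `hic_bin_size`.
#' @param n_tads total number of TADs across the genome (>= 5).
#' @param gene_density_gradient ratio of the expected gene count in the
#'   gene-richest TAD quintile over the gene-poorest quintile.
#' @param n_genes total number of genes.
#' @param n_meth_sites number of assayable HpaII sites (>= 100).
#' @param dmr_fraction fraction of methylation sites planted as
#'   differentially methylated.
#' @param hypo_to_hyper_ratio planted ratio of hypo- to hypermethylated
#'   sites (default 14, i.e. 93% vs 7%).
#' @param dmr_gene_density_skew ratio of planted DMR rate in the
#'   gene-richest over the gene-poorest TAD quintile (1 = uniform).
#' @param meth_depth expected MspI (reference) read depth per site.
#' @param meth_delta planted shift in the latent methylated fraction for
#'   DMR sites (on the 0-1 scale; 0.5 = 50 score units).
#' @param meth_dispersion negative-binomial size parameter for the
#'   methylation counts (smaller = more overdispersed).
#' @param n_signal_regions number of regulatory regions in the shared
#'   DNase/ChIP region universe.
#' @param gain_fraction,loss_fraction fractions of regions planted as DHS
#'   gains/losses; other marks scale from these (see vignette).
#' @param concordance_prob probability that a planted DHS gain also gains
#'   H3K4me1 at the same region.
#' @param bookmarked_fraction fraction of planted DHS gains that already
#'   carry strong WT H3K4me1/me3 ("bookmarked", hence not de novo).
#' @param n_rep_dhs,n_rep_chip replicates per condition (>= 2).
#' @param signal_depth expected read count per replicate for an active
#'   region.
#' @param planted_lfc log2 fold change planted at gain/loss regions.
#' @param de_fraction fraction of genes differentially expressed.
#' @param de_down_fraction fraction of DE genes that are down-regulated
#'   (default 0.77, the "majority >75%" asymmetry).
#' @param hic_bin_size Hi-C bin size in bp (default 100 kb).
#' @param decay_exponent exponent of the contact distance decay
#'   (contacts ~ d^-decay_exponent).
#' @param compartment_strength multiplicative contrast between same- and
#'   cross-compartment contacts (expected counts scaled by 1 +/- strength).
#' @param tad_block_strength within-TAD contact boost (1 + strength).
#' @param domain_score_shift multiplicative inflation of inter-TAD
#'   contacts in TKO for altered TADs (reduces their domain score).
#' @param altered_tad_fraction fraction of TADs flagged as epigenetically
#'   altered (these receive the TKO domain-score shift and extra planted
#'   epigenetic changes).
#' @param altered_gene_skew preference for drawing altered TADs from
#'   gene-dense quintiles (same scale as `dmr_gene_density_skew`).
#' @param reads_per_matrix expected total cis contacts per chromosome
#'   matrix (>= 1e5).
#'
#' @return an object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params(seed = 7, n_tads = 50, n_meth_sites = 2000)
#' p$hypo_to_hyper_ratio
#' @export
sim_params <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_length = 25e6,
                       n_tads = 200L,
                       gene_density_gradient = 12,
                       n_genes = 2000L,
                       n_meth_sites = 50000L,
                       dmr_fraction = 0.015,
                       hypo_to_hyper_ratio = 14,
                       dmr_gene_density_skew = 4,
                       meth_depth = 250,
                       meth_delta = 0.7,
                       meth_dispersion = 10,
                       n_signal_regions = 5000L,
                       gain_fraction = 0.024,
                       loss_fraction = 0.023,
                       concordance_prob = 0.3,
                       bookmarked_fraction = 0.3,
                       n_rep_dhs = 3L,
                       n_rep_chip = 2L,
                       signal_depth = 30,
                       planted_lfc = 2,
                       de_fraction = 0.03,
                       de_down_fraction = 0.77,
                       hic_bin_size = 100000,
                       decay_exponent = 1,
                       compartment_strength = 0.5,
                       tad_block_strength = 1,
                       domain_score_shift = 0.3,
                       altered_tad_fraction = 0.2,
                       altered_gene_skew = 4,
                       reads_per_matrix = 5e5) {
  p <- list(
    seed = check_count(seed, "seed"),
    n_chrom = check_count(n_chrom, "n_chrom", min = 1),
    chrom_length = check_positive(chrom_length, "chrom_length"),
    n_tads = check_count(n_tads, "n_tads", min = 5),
    gene_density_gradient = check_positive(gene_density_gradient,
                                           "gene_density_gradient"),
    n_genes = check_count(n_genes, "n_genes", min = 1),
    n_meth_sites = check_count(n_meth_sites, "n_meth_sites", min = 100),
    dmr_fraction = check_proportion(dmr_fraction, "dmr_fraction"),
    hypo_to_hyper_ratio = check_positive(hypo_to_hyper_ratio,
                                         "hypo_to_hyper_ratio"),
    dmr_gene_density_skew = check_positive(dmr_gene_density_skew,
                                           "dmr_gene_density_skew"),
    meth_depth = check_positive(meth_depth, "meth_depth"),
    meth_delta = check_proportion(meth_delta, "meth_delta"),
    meth_dispersion = check_positive(meth_dispersion, "meth_dispersion"),
    n_signal_regions = check_count(n_signal_regions, "n_signal_regions",
                                   min = 10),
    gain_fraction = check_proportion(gain_fraction, "gain_fraction"),
    loss_fraction = check_proportion(loss_fraction, "loss_fraction"),
    concordance_prob = check_proportion(concordance_prob, "concordance_prob"),
    bookmarked_fraction = check_proportion(bookmarked_fraction,
                                           "bookmarked_fraction"),
    n_rep_dhs = check_count(n_rep_dhs, "n_rep_dhs", min = 2),
    n_rep_chip = check_count(n_rep_chip, "n_rep_chip", min = 2),
    signal_depth = check_positive(signal_depth, "signal_depth"),
    planted_lfc = check_positive(planted_lfc, "planted_lfc"),
    de_fraction = check_proportion(de_fraction, "de_fraction"),
    de_down_fraction = check_proportion(de_down_fraction, "de_down_fraction"),
    hic_bin_size = check_positive(hic_bin_size, "hic_bin_size"),
    decay_exponent = check_positive(decay_exponent, "decay_exponent"),
    compartment_strength = check_positive(compartment_strength,
                                          "compartment_strength",
                                          strict = FALSE),
    tad_block_strength = check_positive(tad_block_strength,
                                        "tad_block_strength", strict = FALSE),
    domain_score_shift = check_positive(domain_score_shift,
                                        "domain_score_shift", strict = FALSE),
    altered_tad_fraction = check_proportion(altered_tad_fraction,
                                            "altered_tad_fraction"),
    altered_gene_skew = check_positive(altered_gene_skew, "altered_gene_skew"),
    reads_per_matrix = check_positive(reads_per_matrix, "reads_per_matrix")
  )
  if (p$compartment_strength >= 1)
    stop("parameter 'compartment_strength' must be < 1", call. = FALSE)
  if (p$chrom_length %% p$hic_bin_size != 0)
    stop("parameter 'chrom_length' must be a multiple of 'hic_bin_size'",
         call. = FALSE)
  bins_per_chrom <- p$chrom_length %/% p$hic_bin_size
  tads_per_chrom <- ceiling(p$n_tads / p$n_chrom)
  if (bins_per_chrom < 2 * tads_per_chrom)
    stop("parameter 'chrom_length' too small: each chromosome must hold ",
         "at least 2 Hi-C bins per TAD", call. = FALSE)
  if (p$reads_per_matrix < 1e5)
    stop("parameter 'reads_per_matrix' must be >= 1e5", call. = FALSE)
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (seed ", x$seed, "):\n", sep = "")
  cat("  genome: ", x$n_chrom, " x ", x$chrom_length / 1e6, " Mb, ",
      x$n_tads, " TADs, ", x$n_genes, " genes\n", sep = "")
  cat("  methylation: ", x$n_meth_sites, " sites, dmr_fraction ",
      x$dmr_fraction, ", hypo:hyper ", x$hypo_to_hyper_ratio, "\n", sep = "")
  cat("  signal: ", x$n_signal_regions, " regions, gain/loss ",
      x$gain_fraction, "/", x$loss_fraction, "\n", sep = "")
  cat("  hic: ", x$hic_bin_size / 1e3, " kb bins, decay ", x$decay_exponent,
      ", shift ", x$domain_score_shift, "\n", sep = "")
  invisible(x)
}
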