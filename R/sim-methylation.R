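#' Simulate a two-condition HpaII/MspI methylation count table
#'
#' Places assayable HpaII sites uniformly along the genome, plants a set of
#' differentially methylated sites skewed toward gene-dense TADs, and draws
#' per-condition HpaII and MspI counts from a negative-binomial model. The
#' methylation-sensitive HpaII digest only cuts unmethylated sites, so the
#' HpaII mean is proportional to (1 - m) for latent methylated fraction m,
#' while the methylation-insensitive MspI digest provides a constant-depth
#' reference. Hypomethylated sites lose `meth_delta` of their methylated
#' fraction in TKO; hypermethylated sites gain it; the planted hypo:hyper
#' mix follows `hypo_to_hyper_ratio`.
#'
#' @param genome a [make_genome()] model.
#' @param params the [sim_params()] used (defaults to `genome$params`).
#' @return a data.frame (wide per-site table) with columns `site_id`,
#'   `chrom`, `start`, `end`, `tad_id`, `gene_quintile`, counts
#'   `hpa_wt`, `msp_wt`, `hpa_tko`, `msp_tko`, and the planted `truth`
#'   label (`"hypo"`, `"hyper"` or `"null"`).
#' @export
simulate_methylation <- function(genome, params = genome$params) {
  stopifnot(inherits(genome, "genome_model"))
  p <- params
  with_stream(p$seed, "meth", {
    n <- p$n_meth_sites
    chrom <- sample(genome$chroms$chrom, n, replace = TRUE,
                    prob = genome$chroms$length)
    pos <- floor(stats::runif(n) *
                 (genome$chroms$length[match(chrom, genome$chroms$chrom)] - 4))
    o <- order(chrom, pos)
    chrom <- chrom[o]; pos <- pos[o]

    # TAD membership via the bin grid (TAD boundaries are bin-aligned)
    bin <- pos %/% p$hic_bin_size
    key <- paste(chrom, bin)
    bkey <- paste(genome$bins$chrom, genome$bins$bin)
    tad_id <- genome$bins$tad_id[match(key, bkey)]
    q <- genome$tads$gene_quintile[match(tad_id, genome$tads$tad_id)]
    q_eff <- ifelse(is.na(q), 1L, q)  # gap sites: baseline weight

    n_dmr <- round(p$dmr_fraction * n)
    truth <- rep("null", n)
    if (p$dmr_fraction > 0 && n_dmr < 1) {
      warning("dmr_fraction * n_meth_sites < 1; no DMRs planted")
      n_dmr <- 0L
    }
    if (n_dmr > 0) {
      w <- p$dmr_gene_density_skew^((q_eff - 1) / 4)
      dmr_idx <- sample.int(n, n_dmr, prob = w)
      hypo <- stats::runif(n_dmr) <
        p$hypo_to_hyper_ratio / (1 + p$hypo_to_hyper_ratio)
      truth[dmr_idx] <- ifelse(hypo, "hypo", "hyper")
    }

    # latent methylated fraction; DMRs start where the planted shift fits
    m_wt <- stats::rbeta(n, 0.8, 0.8)
    is_hypo <- truth == "hypo"; is_hyper <- truth == "hyper"
    m_wt[is_hypo] <- stats::runif(sum(is_hypo), p$meth_delta + 0.1, 0.95)
    m_wt[is_hyper] <- stats::runif(sum(is_hyper), 0.05,
                                   1 - p$meth_delta - 0.05)
    m_tko <- m_wt
    m_tko[is_hypo] <- m_wt[is_hypo] - p$meth_delta
    m_tko[is_hyper] <- m_wt[is_hyper] + p$meth_delta

    # site-level gamma factors shared between conditions (biological
    # site-to-site variability), Poisson counts around them: marginally
    # negative binomial, while preserving the conditional binomial null
    u_hpa <- stats::rgamma(n, shape = p$meth_dispersion,
                           rate = p$meth_dispersion)
    u_msp <- stats::rgamma(n, shape = p$meth_dispersion,
                           rate = p$meth_dispersion)
    data.frame(
      site_id = sprintf("ms_%06d", seq_len(n)),
      chrom = chrom, start = pos, end = pos + 4L,
      tad_id = tad_id, gene_quintile = q,
      hpa_wt = stats::rpois(n, u_hpa * p$meth_depth * (1 - m_wt)),
      msp_wt = stats::rpois(n, u_msp * p$meth_depth),
      hpa_tko = stats::rpois(n, u_hpa * p$meth_depth * (1 - m_tko)),
      msp_tko = stats::rpois(n, u_msp * p$meth_depth),
      truth = truth,
      stringsAsFactors = FALSE
    )
  })
}
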