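#' Simulate binned Hi-C contact matrices
#'
#' Draws, per chromosome, a symmetric matrix of Poisson contact counts
#' around a structured expectation: power-law distance decay
#' (`d^-decay_exponent`), multiplicative A/B compartmentalization (same-
#' compartment bin pairs scaled by `1 + compartment_strength`, cross-
#' compartment by `1 - compartment_strength`), within-TAD insulation
#' (`1 + tad_block_strength`), and -- for the TKO condition only -- an
#' inflation of cross-boundary contacts of epigenetically altered TADs by
#' `1 + domain_score_shift`, which lowers their domain score. Optionally a
#' set of anchor bins receives a pairwise contact boost, emulating the
#' preferential spatial clustering of pluripotency-factor-bound loci that
#' paired-anchor aggregation (PE-SCAN) detects.
#'
#' @param genome a [make_genome()] model.
#' @param params the [sim_params()] used (defaults to `genome$params`).
#' @param condition `"WT"` or `"TKO"`.
#' @param anchor_bins optional named list (per chromosome) of 0-based bin
#'   indices whose pairwise expected contacts are multiplied by
#'   `anchor_boost`.
#' @param anchor_boost multiplier for anchor-anchor bin pairs.
#' @return named list of [contact_matrix()] objects, one per chromosome.
#' @export
simulate_hic <- function(genome, params = genome$params,
                         condition = c("WT", "TKO"),
                         anchor_bins = NULL, anchor_boost = 2) {
  stopifnot(inherits(genome, "genome_model"))
  condition <- match.arg(condition)
  p <- params
  stream <- paste0("hic_", condition)
  with_stream(p$seed, stream, {
    out <- list()
    for (cn in genome$chroms$chrom) {
      b <- genome$bins[genome$bins$chrom == cn, ]
      nb <- nrow(b)
      E <- hic_expectation(b, p, condition, genome$tads)
      if (!is.null(anchor_bins[[cn]]) && length(anchor_bins[[cn]]) >= 2) {
        ai <- anchor_bins[[cn]] + 1L
        boost <- matrix(1, nb, nb)
        boost[ai, ai] <- anchor_boost
        diag(boost) <- 1
        E <- E * boost
      }
      # scale so the expected upper-triangle total equals reads_per_matrix
      ut <- upper.tri(E, diag = TRUE)
      E <- E * (p$reads_per_matrix / sum(E[ut]))
      counts <- matrix(0, nb, nb)
      counts[ut] <- stats::rpois(sum(ut), E[ut])
      counts <- counts + t(counts) - diag(diag(counts))
      out[[cn]] <- contact_matrix(counts, chrom = cn,
                                  bin_size = p$hic_bin_size)
    }
    out
  })
}

# Structured expectation for one chromosome's bins.
hic_expectation <- function(bins, p, condition, tads) {
  nb <- nrow(bins)
  d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
  E <- ifelse(d == 0, 0.5^(-p$decay_exponent), d^(-p$decay_exponent))
  comp <- bins$compartment
  same_comp <- outer(comp, comp, "==")
  E <- E * ifelse(same_comp, 1 + p$compartment_strength,
                  1 - p$compartment_strength)
  tid <- bins$tad_id
  code <- match(tid, unique(tid[!is.na(tid)]))
  code[is.na(code)] <- 0L
  same_tad <- outer(code, code, "==")
  same_tad[code == 0L, ] <- FALSE
  same_tad[, code == 0L] <- FALSE
  E[same_tad] <- E[same_tad] * (1 + p$tad_block_strength)
  if (condition == "TKO" && p$domain_score_shift > 0) {
    alt_ids <- tads$tad_id[tads$altered]
    is_alt <- !is.na(tid) & tid %in% alt_ids
    diff_tad <- !same_tad
    touch_alt <- outer(is_alt, is_alt, "|") & diff_tad
    E[touch_alt] <- E[touch_alt] * (1 + p$domain_score_shift)
  }
  E
}

#' Simulate a differentially-expressed gene list
#'
#' DE genes are drawn uniformly from the gene catalogue -- a proportional,
#' apparently random collection with respect to TAD gene density -- with a
#' planted majority of down-regulated genes.
#'
#' @param genome a [make_genome()] model.
#' @param params the [sim_params()] used (defaults to `genome$params`).
#' @return data.frame with `gene_id`, `chrom`, `tss`, `tad_id`,
#'   `direction` (`"up"`/`"down"`); zero rows when `de_fraction = 0`.
#' @export
simulate_de_genes <- function(genome, params = genome$params) {
  stopifnot(inherits(genome, "genome_model"))
  p <- params
  with_stream(p$seed, "de", {
    n_de <- round(p$de_fraction * nrow(genome$genes))
    if (n_de == 0)
      return(data.frame(gene_id = character(0), chrom = character(0),
                        tss = numeric(0), tad_id = character(0),
                        direction = character(0), stringsAsFactors = FALSE))
    idx <- sort(sample.int(nrow(genome$genes), n_de))
    g <- genome$genes[idx, ]
    data.frame(
      gene_id = g$gene_id, chrom = g$chrom, tss = g$tss, tad_id = g$tad_id,
      direction = ifelse(stats::runif(n_de) < p$de_down_fraction,
                         "down", "up"),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
}
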