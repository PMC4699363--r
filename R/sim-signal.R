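#' Simulate replicated DNase/ChIP count tables over a shared region universe
#'
#' Generates one region universe (placed with the same gene-density
#' preference as genes, since open chromatin and active marks track gene
#' density) and, for each of the five assays (DHS, H3K4me1, H3K4me3,
#' H3K27me3, H3K9me3), per-replicate Poisson counts in both conditions.
#' Planted gains are off-to-on events with log2 fold change `planted_lfc`;
#' losses are the mirror image (on in WT, reduced in TKO). With probability
#' `concordance_prob` a planted DHS gain is also planted as an H3K4me1 gain
#' at the same region. A `bookmarked_fraction` of DHS gains carries strong
#' WT H3K4me1/me3 signal (so they are not de novo sites); the remaining DHS
#' gains are silent in WT for all active marks. Gains of all marks are
#' skewed toward gene-dense (and epigenetically altered) TADs; H3K4me1
#' losses are skewed toward gene-poor TADs; the repressive marks H3K27me3
#' and H3K9me3 receive almost no planted changes.
#'
#' @param genome a [make_genome()] model.
#' @param params the [sim_params()] used (defaults to `genome$params`).
#' @return a named list with one data.frame per mark (`DHS`, `H3K4me1`,
#'   `H3K4me3`, `H3K27me3`, `H3K9me3`). Each has region coordinates,
#'   per-replicate count columns `wt_1..`, `tko_1..`, planted `truth`
#'   (`"gain"`/`"loss"`/`"none"`), planted presence calls `wt_called`,
#'   `tko_called`, and for DHS/H3K4me1 a logical `denovo` truth column.
#' @export
simulate_signal_regions <- function(genome, params = genome$params) {
  stopifnot(inherits(genome, "genome_model"))
  p <- params
  with_stream(p$seed, "signal", {
    n <- p$n_signal_regions
    tads <- genome$tads
    width <- 500L
    # non-overlapping regions (a merged peak universe): width-sized slots
    # within TADs, sampled without replacement with gene-density weights
    # (weighted reservoir keys, Efraimidis-Spirakis)
    slots_per_tad <- pmax(1L, as.integer((tads$end - tads$start) %/% width))
    if (sum(slots_per_tad) < n)
      stop("n_signal_regions exceeds available region slots")
    slot_tad <- rep(seq_len(nrow(tads)), slots_per_tad)
    slot_off <- sequence(slots_per_tad) - 1L
    keys <- stats::runif(length(slot_tad))^(1 / tads$gene_weight[slot_tad])
    idx <- order(keys, decreasing = TRUE)[seq_len(n)]
    ti <- slot_tad[idx]
    start <- tads$start[ti] + slot_off[idx] * width
    o <- order(tads$chrom[ti], start)
    ti <- ti[o]; start <- start[o]
    regions <- data.frame(
      region_id = sprintf("rg_%05d", seq_len(n)),
      chrom = tads$chrom[ti], start = start, end = start + width,
      tad_id = tads$tad_id[ti],
      gene_quintile = tads$gene_quintile[ti],
      stringsAsFactors = FALSE
    )
    q <- regions$gene_quintile
    altered <- tads$altered[ti]

    marks <- c("DHS", "H3K4me1", "H3K4me3", "H3K27me3", "H3K9me3")
    gain_mult <- c(DHS = 1, H3K4me1 = 1.3, H3K4me3 = 1,
                   H3K27me3 = 0.02, H3K9me3 = 0.02)
    loss_mult <- c(DHS = 1, H3K4me1 = 1.3, H3K4me3 = 0.25,
                   H3K27me3 = 0.02, H3K9me3 = 0.02)
    p_on <- c(DHS = 0.7, H3K4me1 = 0.5, H3K4me3 = 0.3,
              H3K27me3 = 0.2, H3K9me3 = 0.2)
    mu_on <- p$signal_depth
    mu_off <- 0.2 * p$signal_depth

    # planted change sets; gains prefer gene-dense + altered TADs
    w_gain <- p$dmr_gene_density_skew^((q - 1) / 4) * (1 + altered)
    w_loss_poor <- p$dmr_gene_density_skew^(-(q - 1) / 4) * (1 + altered)
    w_loss_unif <- 1 + altered
    pick <- function(k, w, exclude = integer(0)) {
      ok <- setdiff(seq_len(n), exclude)
      ok[sample.int(length(ok), min(k, length(ok)), prob = w[ok])]
    }

    # WT presence states first, then planted changes conditioned on them
    on_wt <- lapply(p_on, function(pp) stats::runif(n) < pp)

    gain_idx <- list(); loss_idx <- list()
    gain_idx$DHS <- pick(round(p$gain_fraction * n * gain_mult["DHS"]), w_gain)
    loss_idx$DHS <- pick(round(p$loss_fraction * n * loss_mult["DHS"]),
                         w_loss_unif, gain_idx$DHS)
    is_dhs_gain <- seq_len(n) %in% gain_idx$DHS
    on_wt$DHS[is_dhs_gain] <- FALSE      # new sites: closed in WT
    on_wt$DHS[loss_idx$DHS] <- TRUE
    bookmarked <- rep(FALSE, n)
    bookmarked[gain_idx$DHS] <- stats::runif(length(gain_idx$DHS)) <
      p$bookmarked_fraction
    on_wt$H3K4me1[is_dhs_gain] <- bookmarked[is_dhs_gain]
    on_wt$H3K4me3[is_dhs_gain] <- bookmarked[is_dhs_gain]

    # concordant H3K4me1 gains at planted DHS gains; remaining H3K4me1
    # gains arise de novo at regions inactive for DHS and H3K4me3 in WT
    coupled <- gain_idx$DHS[stats::runif(length(gain_idx$DHS)) <
                            p$concordance_prob]
    k1_target <- round(p$gain_fraction * n * gain_mult["H3K4me1"])
    w_k1 <- w_gain * ifelse(!on_wt$DHS & !on_wt$H3K4me3, 1, 0.02)
    extra_k1 <- pick(max(0, k1_target - length(coupled)), w_k1,
                     union(gain_idx$DHS, loss_idx$DHS))
    gain_idx$H3K4me1 <- union(coupled, extra_k1)
    loss_idx$H3K4me1 <- pick(round(p$loss_fraction * n *
                                   loss_mult["H3K4me1"]),
                             w_loss_poor, gain_idx$H3K4me1)
    for (mk in c("H3K4me3", "H3K27me3", "H3K9me3")) {
      gain_idx[[mk]] <- pick(round(p$gain_fraction * n * gain_mult[mk]),
                             w_gain)
      loss_idx[[mk]] <- pick(round(p$loss_fraction * n * loss_mult[mk]),
                             w_loss_unif, gain_idx[[mk]])
    }

    # expected WT rate per mark x region, then TKO rate from planted truth
    mu_wt <- list(); mu_tko <- list(); truth <- list()
    for (mk in marks) {
      tr <- rep("none", n)
      tr[gain_idx[[mk]]] <- "gain"
      tr[loss_idx[[mk]]] <- "loss"
      ow <- on_wt[[mk]]
      ow[tr == "gain"] <- ow[tr == "gain"] &
        mk %in% c("H3K4me1", "H3K4me3") & bookmarked[tr == "gain"]
      ow[tr == "loss"] <- TRUE
      mw <- ifelse(ow, mu_on * exp(stats::rnorm(n, 0, 0.2)), mu_off)
      if (mk %in% c("H3K4me1", "H3K4me3"))
        mw[is_dhs_gain & bookmarked] <- 1.5 * mu_on  # clearly above threshold
      mt <- mw
      mt[tr == "gain"] <- mw[tr == "gain"] * 2^p$planted_lfc
      mt[tr == "loss"] <- mw[tr == "loss"] * 2^(-p$planted_lfc)
      mu_wt[[mk]] <- mw; mu_tko[[mk]] <- mt
      truth[[mk]] <- tr
      on_wt[[mk]] <- ow
    }

    call_thr <- 0.5 * mu_on
    out <- list()
    for (mk in marks) {
      n_rep <- if (mk == "DHS") p$n_rep_dhs else p$n_rep_chip
      f_wt <- exp(stats::rnorm(n_rep, 0, 0.1))
      f_tko <- exp(stats::rnorm(n_rep, 0, 0.1))
      tab <- regions
      for (r in seq_len(n_rep))
        tab[[paste0("wt_", r)]] <- stats::rpois(n, mu_wt[[mk]] * f_wt[r])
      for (r in seq_len(n_rep))
        tab[[paste0("tko_", r)]] <- stats::rpois(n, mu_tko[[mk]] * f_tko[r])
      tab$truth <- truth[[mk]]
      tab$wt_called <- mu_wt[[mk]] >= call_thr
      tab$tko_called <- mu_tko[[mk]] >= call_thr
      if (mk == "DHS")
        tab$denovo <- truth$DHS == "gain" & !bookmarked
      if (mk == "H3K4me1")
        tab$denovo <- truth$H3K4me1 == "gain" &
          mu_wt$DHS < call_thr & mu_wt$H3K4me3 < call_thr
      out[[mk]] <- tab
    }
    attr(out, "coupled_regions") <- regions$region_id[coupled]
    out
  })
}
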