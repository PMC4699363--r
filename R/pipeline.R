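#' Pipeline run configuration
#'
#' Validated configuration for [run_pipeline()]: analysis thresholds (all
#' anchored to the defaults used throughout the package), the root seed,
#' stage toggles and simulation parameters. Unknown keys are rejected.
#'
#' @param seed root seed (also used by the simulators).
#' @param p_threshold methylation binomial significance (default 1e-6).
#' @param fdr_threshold DHS FDR (default 0.05).
#' @param chip_p_threshold ChIP raw-p threshold (default 0.001).
#' @param delta_threshold stringent methylation score delta (default 25).
#' @param window methylation clustering window, bp (default 20000).
#' @param min_sites minimum sites per qualifying window (default 5).
#' @param draws null draws for the clustering test (default 1000).
#' @param tss_window TSS proximity half-width, bp (default 2500).
#' @param bin_size Hi-C bin size, bp (default 100000).
#' @param wt_quantile de novo WT-signal threshold quantile (default 0.25).
#' @param stages character vector of stages to run, a subset of
#'   `c("methylation", "sites", "tads", "hic")`.
#' @param sim a [sim_params()] object (defaults to `sim_params(seed)`).
#' @param ... unknown keys: rejected with an error.
#' @return object of class `run_config` with a `hash` attribute that
#'   changes whenever any threshold changes.
#' @export
run_config <- function(seed = 1L,
                       p_threshold = 1e-6,
                       fdr_threshold = 0.05,
                       chip_p_threshold = 0.001,
                       delta_threshold = 25,
                       window = 20000,
                       min_sites = 5,
                       draws = 1000,
                       tss_window = 2500,
                       bin_size = 100000,
                       wt_quantile = 0.25,
                       stages = c("methylation", "sites", "tads", "hic"),
                       sim = NULL, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  for (nm in c("p_threshold", "fdr_threshold", "chip_p_threshold",
               "delta_threshold", "window", "min_sites", "draws",
               "tss_window", "bin_size", "wt_quantile"))
    check_positive(get(nm), nm)
  bad <- setdiff(stages, c("methylation", "sites", "tads", "hic"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(sim)) sim <- sim_params(seed = seed, hic_bin_size = bin_size)
  cfg <- list(seed = check_count(seed, "seed"),
              p_threshold = p_threshold, fdr_threshold = fdr_threshold,
              chip_p_threshold = chip_p_threshold,
              delta_threshold = delta_threshold, window = window,
              min_sites = min_sites, draws = draws,
              tss_window = tss_window, bin_size = bin_size,
              wt_quantile = wt_quantile, stages = stages, sim = sim)
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(cfg), tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys map to [run_config()] arguments; a `sim:` block maps to
#' [sim_params()] arguments.
#'
#' @param path YAML file path.
#' @return a `run_config` object.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    y$sim <- do.call(sim_params, y$sim)
  }
  do.call(run_config, y)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates the two-condition dataset, then runs the enabled analysis
#' stages in dependency order: differential methylation (scores, binomial
#' tests, stringent set, window clustering, chromatin-state composition),
#' differential DNase/ChIP calling (with de novo site definition and
#' cross-mark overlap/concordance), TAD quintile enrichment (gene-content
#' ranking, enrichment ratios, DE-gene distributions, TSS-proximal
#' changes), and Hi-C topology (balancing, compartment PC1, distance
#' decay, domain scores and their WT/TKO comparison, delta-score
#' quintiles). The run is deterministic given the configuration; re-running
#' with the same config overwrites outputs identically.
#'
#' @param config a [run_config()] object (or path to a YAML config).
#' @param outdir optional directory; when given, fixture and result tables
#'   are written there (BED/TSV/COO/JSON).
#' @return a report list with one element per executed stage plus a
#'   `provenance` block (config hash, seed, package version).
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  sim <- config$sim
  report <- list()
  t0 <- Sys.time()
  stage_log <- function(stage, n_in, n_out) {
    message(sprintf("[%s] inputs=%d outputs=%d elapsed=%.1fs", stage,
                    n_in, n_out, as.numeric(Sys.time() - t0, units = "secs")))
  }

  genome <- make_genome(sim)
  meth <- simulate_methylation(genome)
  signal <- simulate_signal_regions(genome)
  de <- simulate_de_genes(genome)
  hic_wt <- simulate_hic(genome, condition = "WT")
  hic_tko <- simulate_hic(genome, condition = "TKO")
  stage_log("simulate", 0L, nrow(meth) + nrow(signal$DHS))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_bed(data.frame(chrom = genome$tads$chrom,
                         start = genome$tads$start,
                         end = genome$tads$end,
                         name = genome$tads$tad_id),
              file.path(outdir, "tads.bed"))
    write_bed(data.frame(chrom = genome$genes$chrom,
                         start = genome$genes$start,
                         end = genome$genes$end,
                         name = genome$genes$gene_id,
                         score = 0,
                         strand = genome$genes$strand),
              file.path(outdir, "genes.bed"))
    write_bed(data.frame(chrom = genome$states$chrom,
                         start = genome$states$start,
                         end = genome$states$end,
                         name = genome$states$state),
              file.path(outdir, "states.bed"))
    write_counts(counts_long(meth, c("WT:hpa" = "hpa_wt",
                                     "WT:msp" = "msp_wt",
                                     "TKO:hpa" = "hpa_tko",
                                     "TKO:msp" = "msp_tko")),
                 file.path(outdir, "methylation_counts.tsv"))
    write_coo(hic_wt, file.path(outdir, "hic_wt.coo"))
    write_coo(hic_tko, file.path(outdir, "hic_tko.coo"))
  }

  mtab <- NULL
  if ("methylation" %in% config$stages) {
    mtab <- meth_diff(meth, p_threshold = config$p_threshold,
                      delta_threshold = config$delta_threshold)
    dmr <- mtab[mtab$direction != "none", ]
    wc <- window_cluster_test(dmr, mtab, window = config$window,
                              min_sites = config$min_sites,
                              draws = config$draws,
                              seed = stream_seed(config$seed, "analysis"))
    sc <- state_composition(dmr, genome$states, assayable = mtab,
                            seed = stream_seed(config$seed, "analysis"))
    report$methylation <- list(
      table = mtab,
      n_significant = sum(mtab$direction != "none"),
      n_hypo = sum(mtab$direction == "hypo"),
      n_hyper = sum(mtab$direction == "hyper"),
      n_stringent_hypo = sum(mtab$stringent & mtab$direction == "hypo"),
      n_stringent_hyper = sum(mtab$stringent & mtab$direction == "hyper"),
      window_cluster = wc, state_composition = sc)
    if (!is.null(outdir)) {
      sig <- mtab[mtab$direction != "none", ]
      write_bed(data.frame(chrom = sig$chrom, start = sig$start,
                           end = sig$end, name = sig$direction,
                           score = round(-log10(pmax(sig$p, 1e-300)), 2)),
                file.path(outdir, "dmr.bed"))
      jsonlite::write_json(
        list(observed = wc$observed, draws = wc$draws, p = wc$p),
        file.path(outdir, "window_cluster.json"), auto_unbox = TRUE)
      utils::write.table(sc, file.path(outdir, "state_composition.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    stage_log("methylation", nrow(mtab), sum(mtab$direction != "none"))
  }

  called <- NULL
  if ("sites" %in% config$stages) {
    called <- list()
    for (mk in names(signal)) {
      tab <- signal[[mk]]
      wt_cols <- grep("^wt_", names(tab), value = TRUE)
      tko_cols <- grep("^tko_", names(tab), value = TRUE)
      f <- size_factors(tab[, c(wt_cols, tko_cols)])
      res <- test_regions(tab[, wt_cols], tab[, tko_cols],
                          f[seq_along(wt_cols)],
                          f[length(wt_cols) + seq_along(tko_cols)])
      tab$lfc <- res$lfc; tab$p <- res$p
      mode <- if (mk == "DHS") "dhs" else "chip"
      called[[mk]] <- call_changes(tab, mode = mode,
                                   q_threshold = config$fdr_threshold,
                                   p_threshold = config$chip_p_threshold)
    }
    # WT signal tracks (normalized mean WT coverage + WT presence calls)
    track <- function(mk) {
      tab <- called[[mk]]
      wt_cols <- grep("^wt_", names(tab), value = TRUE)
      f <- size_factors(tab[, grep("^(wt|tko)_", names(tab))])
      data.frame(chrom = tab$chrom, start = tab$start, end = tab$end,
                 signal = rowMeans(sweep(as.matrix(tab[, wt_cols]), 2,
                                         f[seq_along(wt_cols)], "/")),
                 called = tab$wt_called, stringsAsFactors = FALSE)
    }
    dhs <- called$DHS
    denovo_dhs <- call_denovo_dhs(
      dhs[dhs$tko_called, c("region_id", "chrom", "start", "end")],
      dhs[dhs$wt_called, c("region_id", "chrom", "start", "end")],
      track("H3K4me1"), track("H3K4me3"),
      wt_quantile = config$wt_quantile)
    k1 <- called$H3K4me1
    denovo_k4me1 <- call_denovo_k4me1(
      k1[k1$tko_called, c("region_id", "chrom", "start", "end")],
      k1[k1$wt_called, c("region_id", "chrom", "start", "end")],
      track("H3K4me3"), track("DHS"),
      wt_quantile = config$wt_quantile)
    universe <- called$DHS[, c("chrom", "start", "end")]
    ovl <- overlap_test(
      called$DHS[called$DHS$label == "gain", c("chrom", "start", "end")],
      called$H3K4me1[called$H3K4me1$label == "gain",
                     c("chrom", "start", "end")],
      universe)
    conc <- concordance(called$DHS, called$H3K4me1)
    report$sites <- list(
      called = called, denovo_dhs = denovo_dhs,
      denovo_k4me1 = denovo_k4me1,
      n_gain = vapply(called, function(x) sum(x$label == "gain"),
                      numeric(1)),
      n_loss = vapply(called, function(x) sum(x$label == "loss"),
                      numeric(1)),
      overlap_dhs_k4me1 = ovl, concordance_dhs_k4me1 = conc)
    if (!is.null(outdir)) {
      for (mk in names(called)) {
        lab <- called[[mk]]
        utils::write.table(
          lab[, setdiff(names(lab), "denovo")],
          file.path(outdir, paste0("diff_", mk, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
      write_bed(denovo_dhs[, c("chrom", "start", "end")],
                file.path(outdir, "denovo_dhs.bed"))
      jsonlite::write_json(
        list(overlap = unclass(ovl),
             concordance = list(n = conc$n, spearman = conc$spearman)),
        file.path(outdir, "overlap.json"), auto_unbox = TRUE)
    }
    stage_log("sites", nrow(signal$DHS),
              sum(vapply(called, function(x) sum(x$label != "none"),
                         numeric(1))))
  }

  if ("tads" %in% config$stages) {
    tads <- genome$tads
    gene_tss <- data.frame(chrom = genome$genes$chrom,
                           start = genome$genes$tss,
                           end = genome$genes$tss + 1)
    gene_counts <- assign_sites_to_tads(gene_tss, tads)$counts
    bins <- quintile_bins(gene_counts)
    gene_pct <- bin_percentages(gene_counts, bins, tads)
    quint <- list(gene_pct = gene_pct)
    if (!is.null(mtab)) {
      for (dir in c("hypo", "hyper")) {
        ss <- mtab[mtab$direction == dir, ]
        cnt <- assign_sites_to_tads(ss, tads)$counts
        ref <- assign_sites_to_tads(mtab, tads)$counts
        ref_pct <- bin_percentages(ref, bins)$pct
        if (sum(cnt) > 0) {
          quint[[paste0(dir, "_pct")]] <- bin_percentages(cnt, bins)
          quint[[paste0(dir, "_ratio")]] <- enrichment_ratio(
            bin_percentages(cnt, bins)$pct, ref_pct)
        }
        if (sum(cnt) >= 25 && all(ref_pct > 0))
          quint[[paste0(dir, "_chisq")]] <- chisq_nonuniformity(
            vapply(1:5, function(b) sum(cnt[bins == b]), numeric(1)),
            ref_pct / 100)
      }
    }
    de_summary <- NULL
    if (nrow(de) > 0) {
      de_tss <- data.frame(chrom = de$chrom, start = de$tss,
                           end = de$tss + 1)
      de_counts <- assign_sites_to_tads(de_tss, tads)$counts
      de_summary <- list(pct = bin_percentages(de_counts, bins))
      if (sum(de_counts) >= 25)
        de_summary$chisq <- chisq_nonuniformity(
          vapply(1:5, function(b) sum(de_counts[bins == b]), numeric(1)),
          bin_percentages(gene_counts, bins)$pct / 100)
    }
    tssp <- NULL
    if (!is.null(called) && nrow(de) > 0) {
      gain <- called$DHS[called$DHS$label == "gain", ]
      loss <- called$DHS[called$DHS$label == "loss", ]
      up <- genome$genes[genome$genes$gene_id %in%
                           de$gene_id[de$direction == "up"], ]
      down <- genome$genes[genome$genes$gene_id %in%
                             de$gene_id[de$direction == "down"], ]
      tssp <- rbind(
        cbind(genes = "up", tss_proximal_changes(
          up, list(gain = gain, loss = loss), window = config$tss_window)),
        cbind(genes = "down", tss_proximal_changes(
          down, list(gain = gain, loss = loss),
          window = config$tss_window)))
    }
    report$tads <- list(bins = bins, quintiles = quint, de = de_summary,
                        tss_proximal = tssp)
    if (!is.null(outdir))
      utils::write.table(gene_pct, file.path(outdir, "tad_quintiles.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    stage_log("tads", nrow(tads), length(quint))
  }

  if ("hic" %in% config$stages) {
    per_chrom <- list()
    ds_wt <- list(); ds_tko <- list()
    for (cn in genome$chroms$chrom) {
      bal_wt <- balance(hic_wt[[cn]])
      bal_tko <- balance(hic_tko[[cn]])
      bbins <- genome$bins[genome$bins$chrom == cn, ]
      tss_cn <- genome$genes$tss[genome$genes$chrom == cn]
      gd <- tabulate(tss_cn %/% config$bin_size + 1L, nbins = nrow(bbins))
      pc <- compartment_pc1(bal_wt, gd)
      dec_wt <- fit_decay_exponent(hic_wt[[cn]])
      ds_wt[[cn]] <- domain_score(bal_wt, genome$tads, condition = "WT")
      ds_tko[[cn]] <- domain_score(bal_tko, genome$tads,
                                   condition = "TKO")
      per_chrom[[cn]] <- list(pc1 = pc, decay_exponent = dec_wt)
    }
    dsw <- do.call(rbind, ds_wt); dst <- do.call(rbind, ds_tko)
    cmp <- compare_domain_scores(dsw, dst)
    changes <- NULL; dq <- NULL
    if (!is.null(called) && !is.null(mtab)) {
      tads <- genome$tads
      keep <- tads$tad_id %in% cmp$deltas$tad_id
      tt <- tads[keep, ]
      m <- match(cmp$deltas$tad_id, tt$tad_id)
      chg <- function(df) assign_sites_to_tads(df, tt)$counts[m]
      changes <- data.frame(
        dmr = chg(mtab[mtab$direction != "none", ]),
        dhs = chg(called$DHS[called$DHS$label != "none", ]),
        k4me1 = chg(called$H3K4me1[called$H3K4me1$label != "none", ]),
        k4me3 = chg(called$H3K4me3[called$H3K4me3$label != "none", ]))
      de_counts <- chg(data.frame(chrom = de$chrom, start = de$tss,
                                  end = de$tss + 1))
      if (sum(changes) >= 25)
        dq <- delta_score_quintiles(
          cmp$deltas$delta, changes,
          controls = list(
            gene_count = tt$gene_count[m],
            tad_size = (tt$end - tt$start)[m],
            de_genes = de_counts))
    }
    report$hic <- list(per_chrom = per_chrom,
                       domain_scores_wt = dsw, domain_scores_tko = dst,
                       comparison = cmp, delta_quintiles = dq)
    if (!is.null(outdir)) {
      ds_all <- rbind(dsw, dst)
      utils::write.table(ds_all, file.path(outdir, "domain_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    stage_log("hic", length(genome$chroms$chrom), nrow(dsw))
  }

  report$provenance <- list(
    config_hash = attr(config, "hash"),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("tadscape")),
    stages = config$stages)
  report$genome <- genome
  report
}
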