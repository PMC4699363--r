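#' Generate a miniature genome model
#'
#' Builds the deterministic scaffold that all simulators share: equal-length
#' chromosomes partitioned into Hi-C bins, an ordered non-overlapping TAD
#' partition aligned to bin boundaries (with occasional inter-TAD gap bins),
#' alternating A/B compartment blocks, genes placed with a planted
#' gene-density gradient across TAD quintiles (gene-dense TADs
#' preferentially fall in the A compartment), a chromatin-state segmentation
#' tiling each chromosome, and a set of "altered" TADs drawn preferentially
#' from gene-dense quintiles that downstream simulators use to couple
#' epigenetic change with topological change.
#'
#' @param params a [sim_params()] object.
#' @return an object of class `genome_model`: a list with elements
#'   `chroms` (name, length), `bins` (per Hi-C bin: chrom, bin index, start,
#'   end, compartment, tad_id), `tads` (chrom, start, end, tad_id,
#'   gene_quintile 1-5, gene_weight, gene_count, compartment, altered),
#'   `genes` (chrom, start, end, strand, tss, gene_id, tad_id),
#'   `states` (chrom, start, end, state) and `params`.
#' @examples
#' g <- make_genome(sim_params(seed = 1, n_tads = 20, n_genes = 200,
#'                             chrom_length = 5e6, n_chrom = 1))
#' table(g$tads$gene_quintile)
#' @export
make_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_stream(params$seed, "genome", build_genome(params))
}

build_genome <- function(p) {
  bs <- p$hic_bin_size
  n_bins <- as.integer(p$chrom_length %/% bs)
  chrom_names <- sprintf("chr%d", seq_len(p$n_chrom))
  chroms <- data.frame(chrom = chrom_names, length = p$chrom_length,
                       stringsAsFactors = FALSE)

  # TADs per chromosome, as even as possible
  tad_n <- rep(p$n_tads %/% p$n_chrom, p$n_chrom)
  extra <- p$n_tads %% p$n_chrom
  if (extra > 0) tad_n[seq_len(extra)] <- tad_n[seq_len(extra)] + 1L

  tads <- list(); bins <- list()
  tad_id0 <- 0L
  for (ci in seq_len(p$n_chrom)) {
    t <- tad_n[ci]
    # sizes in bins: 2 each, leftover bins grow random TADs (70%) or
    # become inter-TAD gaps (30%)
    sizes <- rep(2L, t)
    leftover <- n_bins - 2L * t
    n_grow <- round(0.7 * leftover)
    if (n_grow > 0) {
      grow <- sample.int(t, n_grow, replace = TRUE)
      gt <- tabulate(grow, nbins = t)
      sizes <- sizes + gt
    }
    n_gap_bins <- leftover - n_grow
    # distribute gap bins into t+1 junctions (before/after/between TADs)
    gaps <- integer(t + 1L)
    if (n_gap_bins > 0) {
      at <- sample.int(t + 1L, n_gap_bins, replace = TRUE)
      gaps <- tabulate(at, nbins = t + 1L)
    }
    # lay out: gap[1], tad1, gap[2], tad2, ...
    tad_bin <- integer(n_bins)  # 0 = gap, else local tad index
    pos <- 0L
    for (k in seq_len(t)) {
      pos <- pos + gaps[k]
      tad_bin[(pos + 1L):(pos + sizes[k])] <- k
      pos <- pos + sizes[k]
    }
    local_ids <- tad_id0 + seq_len(t)
    starts <- vapply(seq_len(t), function(k) min(which(tad_bin == k)) - 1L, 1L)
    ends <- vapply(seq_len(t), function(k) max(which(tad_bin == k)), 1L)
    tads[[ci]] <- data.frame(
      chrom = chrom_names[ci],
      start = starts * bs, end = ends * bs,
      tad_id = sprintf("tad_%04d", local_ids),
      stringsAsFactors = FALSE
    )

    # compartment blocks over bins: alternating A/B runs of 8-16 bins
    comp <- character(0)
    lab <- sample(c("A", "B"), 1)
    while (length(comp) < n_bins) {
      comp <- c(comp, rep(lab, sample(8:16, 1)))
      lab <- if (lab == "A") "B" else "A"
    }
    comp <- comp[seq_len(n_bins)]
    bins[[ci]] <- data.frame(
      chrom = chrom_names[ci], bin = seq_len(n_bins) - 1L,
      start = (seq_len(n_bins) - 1L) * bs, end = seq_len(n_bins) * bs,
      compartment = comp,
      tad_id = ifelse(tad_bin == 0L, NA_character_,
                      sprintf("tad_%04d", tad_id0 + tad_bin)),
      stringsAsFactors = FALSE
    )
    tad_id0 <- tad_id0 + t
  }
  tads <- do.call(rbind, tads)
  bins <- do.call(rbind, bins)
  rownames(tads) <- rownames(bins) <- NULL

  # TAD compartment = majority vote of its bins
  tad_comp <- vapply(split(bins$compartment[!is.na(bins$tad_id)],
                           bins$tad_id[!is.na(bins$tad_id)]),
                     function(v) names(which.max(table(v))), "")
  tads$compartment <- unname(tad_comp[tads$tad_id])

  # gene-density quintiles: A-compartment TADs preferentially gene-dense
  score <- 1.2 * (tads$compartment == "A") + stats::rnorm(nrow(tads))
  rk <- rank(score, ties.method = "first")
  tads$gene_quintile <- as.integer(ceiling(5 * rk / nrow(tads)))
  tads$gene_weight <- p$gene_density_gradient^((tads$gene_quintile - 1) / 4)

  # genes: multinomial over TADs by weight, uniform position within TAD
  gene_counts <- as.integer(stats::rmultinom(
    1, p$n_genes, tads$gene_weight / sum(tads$gene_weight)))
  tads$gene_count <- gene_counts
  gi <- rep(seq_len(nrow(tads)), gene_counts)
  glen <- pmin(round(stats::runif(p$n_genes, 5e3, 5e4)),
               (tads$end - tads$start)[gi] - 1)
  gstart <- tads$start[gi] + floor(stats::runif(p$n_genes) *
                                   (tads$end[gi] - tads$start[gi] - glen))
  strand <- sample(c("+", "-"), p$n_genes, replace = TRUE)
  genes <- data.frame(
    chrom = tads$chrom[gi], start = gstart, end = gstart + glen,
    strand = strand,
    tss = ifelse(strand == "+", gstart, gstart + glen - 1),
    gene_id = sprintf("gene_%05d", seq_len(p$n_genes)),
    tad_id = tads$tad_id[gi],
    stringsAsFactors = FALSE
  )
  genes <- genes[order(genes$chrom, genes$start), ]
  rownames(genes) <- NULL

  # altered TADs: weighted toward gene-dense quintiles
  n_alt <- round(p$altered_tad_fraction * nrow(tads))
  w_alt <- p$altered_gene_skew^((tads$gene_quintile - 1) / 4)
  alt_idx <- sample.int(nrow(tads), n_alt, prob = w_alt)
  tads$altered <- FALSE
  tads$altered[alt_idx] <- TRUE

  states <- build_states(p, chroms, bins, genes)

  structure(list(chroms = chroms, bins = bins, tads = tads, genes = genes,
                 states = states, params = p),
            class = "genome_model")
}

# Chromatin-state segmentation: 2-kb tiles labelled by precedence
# promoter > transcribed > enhancer > heterochromatin > other, then merged.
build_states <- function(p, chroms, bins, genes) {
  tile <- 2000L
  out <- list()
  for (ci in seq_len(nrow(chroms))) {
    cn <- chroms$chrom[ci]
    n_tiles <- as.integer(chroms$length[ci] %/% tile)
    lab <- rep("other", n_tiles)
    bchrom <- bins[bins$chrom == cn, ]
    tile_bin <- pmin(((seq_len(n_tiles) - 1L) * tile) %/% p$hic_bin_size,
                     nrow(bchrom) - 1L)
    in_a <- bchrom$compartment[tile_bin + 1L] == "A"
    lab[!in_a & stats::runif(n_tiles) < 0.5] <- "heterochromatin"
    lab[in_a & stats::runif(n_tiles) < 0.10] <- "enhancer"
    lab[!in_a & stats::runif(n_tiles) < 0.02] <- "enhancer"
    g <- genes[genes$chrom == cn, ]
    if (nrow(g)) {
      for (k in seq_len(nrow(g))) {
        t0 <- max(0L, g$start[k] %/% tile)
        t1 <- min(n_tiles - 1L, (g$end[k] - 1L) %/% tile)
        lab[(t0:t1) + 1L] <- "transcribed"
      }
      p0 <- pmax(0L, (g$tss - 1000L) %/% tile)
      p1 <- pmin(n_tiles - 1L, (g$tss + 999L) %/% tile)
      pt <- unique(unlist(mapply(seq, p0, p1, SIMPLIFY = FALSE)))
      lab[pt + 1L] <- "promoter"
    }
    r <- rle(lab)
    ends <- cumsum(r$lengths) * tile
    out[[ci]] <- data.frame(
      chrom = cn, start = ends - r$lengths * tile, end = ends,
      state = r$values, stringsAsFactors = FALSE
    )
  }
  states <- do.call(rbind, out)
  rownames(states) <- NULL
  states
}

#' @export
print.genome_model <- function(x, ...) {
  cat("Genome model: ", nrow(x$chroms), " chromosomes (",
      sum(x$chroms$length) / 1e6, " Mb), ", nrow(x$tads), " TADs, ",
      nrow(x$genes), " genes, ", nrow(x$states), " state segments\n",
      sep = "")
  cat("  altered TADs: ", sum(x$tads$altered), "; A-compartment bins: ",
      sum(x$bins$compartment == "A"), "/", nrow(x$bins), "\n", sep = "")
  invisible(x)
}
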