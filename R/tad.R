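#' Assign sites to TADs by interval midpoint
#'
#' A site belongs to the TAD containing its midpoint (0-based half-open,
#' so a midpoint on a TAD start boundary belongs to that TAD). Sites in
#' inter-TAD gaps are counted in an unassigned bucket and excluded from
#' downstream percentages, keeping totals auditable.
#'
#' @param sites data.frame with `chrom`, `start`, `end`.
#' @param tads data.frame with `chrom`, `start`, `end`, `tad_id`.
#' @return list with `counts` (named integer vector, one entry per TAD in
#'   input order) and `unassigned` (count of gap sites).
#' @export
assign_sites_to_tads <- function(sites, tads) {
  idx <- if (nrow(sites)) midpoint_assign(sites, tads) else integer(0)
  counts <- tabulate(idx[!is.na(idx)], nbins = nrow(tads))
  names(counts) <- tads$tad_id
  list(counts = counts, unassigned = sum(is.na(idx)))
}

#' Split TADs into quintiles by a ranking key
#'
#' TADs are stably sorted ascending by `key` (ties broken by input,
#' i.e. genomic, order) and split into five contiguous groups with equal
#' TAD counts; a remainder is distributed one extra TAD per bin from the
#' lowest bin upward. Bin 1 holds the 20% of TADs with the lowest key.
#'
#' @param key numeric vector, one value per TAD (no NAs).
#' @return integer vector of bin indices 1-5 aligned with `key`, with a
#'   `sizes` attribute.
#' @examples
#' quintile_bins(c(5, 1, 4, 2, 3, 6, 0, 7, 9, 8, 10, 11))  # sizes 3,3,2,2,2
#' @export
quintile_bins <- function(key) {
  n <- length(key)
  if (n < 5) stop("need at least 5 TADs to form quintiles")
  if (anyNA(key)) stop("ranking key contains NA")
  sizes <- rep(n %/% 5L, 5L)
  rem <- n %% 5L
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ord <- order(key)  # stable: ties keep genomic order
  bin <- integer(n)
  bin[ord] <- rep(1:5, times = sizes)
  attr(bin, "sizes") <- sizes
  bin
}

#' Per-bin percentages of a per-TAD feature count
#'
#' @param counts non-negative numeric vector, one value per TAD.
#' @param bins quintile bin index per TAD (from [quintile_bins()]).
#' @param tads optional TAD data.frame (`start`, `end`) to also report the
#'   genomic-size percentage of each bin as a baseline.
#' @return data.frame with `bin`, `pct` (sums to 100) and, when `tads`
#'   is supplied, `size_pct`.
#' @export
bin_percentages <- function(counts, bins, tads = NULL) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("all-zero counts: percentages undefined")
  pct <- vapply(1:5, function(b) 100 * sum(counts[bins == b]) / total,
                numeric(1))
  out <- data.frame(bin = 1:5, pct = pct)
  if (!is.null(tads)) {
    sz <- tads$end - tads$start
    out$size_pct <- vapply(1:5, function(b)
      100 * sum(sz[bins == b]) / sum(sz), numeric(1))
  }
  out
}

#' Enrichment ratio of two per-bin percentage profiles
#'
#' Ratio of the percentage of a changed feature over the percentage of a
#' reference feature per bin; 1 means the change is distributed
#' proportionally to the reference. Bins with zero reference percentage
#' get `NA` with a warning.
#'
#' @param pct_changed,pct_reference numeric vectors of per-bin percentages.
#' @return numeric vector of ratios.
#' @export
enrichment_ratio <- function(pct_changed, pct_reference) {
  stopifnot(length(pct_changed) == length(pct_reference))
  out <- pct_changed / pct_reference
  zero <- pct_reference == 0
  if (any(zero)) {
    warning("zero reference percentage in bin(s) ",
            paste(which(zero), collapse = ", "), "; ratio undefined")
    out[zero] <- NA_real_
  }
  out
}

#' Chi-squared test for non-uniform distribution over bins
#'
#' Pearson chi-squared of observed per-bin counts against expected
#' proportions (e.g. the reference feature's distribution), with
#' `length(observed) - 1` degrees of freedom.
#'
#' @param observed per-bin counts.
#' @param expected_prop expected proportions (normalized internally).
#' @return list with `statistic`, `df`, `p`.
#' @export
chisq_nonuniformity <- function(observed, expected_prop) {
  stopifnot(length(observed) == length(expected_prop))
  total <- sum(observed)
  expected <- total * expected_prop / sum(expected_prop)
  if (any(expected <= 0) || total < 25)
    stop("expected counts must be positive and total >= 25; ",
         "use an exact test for smaller samples")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Percentage of genes with a changed site near their TSS
#'
#' A gene is counted when any changed site's midpoint falls within
#' `[TSS - window, TSS + window)`.
#'
#' @param genes data.frame with `chrom`, `tss`.
#' @param site_sets named list of data.frames (`chrom`, `start`, `end`)
#'   of changed sites, e.g. `list(gain = ..., loss = ...)`.
#' @param window half-width in bp (default 2500).
#' @return data.frame with one row per site set: `set`, `n_genes`,
#'   `n_hit`, `pct`.
#' @export
tss_proximal_changes <- function(genes, site_sets, window = 2500) {
  stopifnot(is.list(site_sets), !is.null(names(site_sets)))
  tss_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = pmax(1, genes$tss - window + 1),
                              end = genes$tss + window))
  rows <- lapply(names(site_sets), function(nm) {
    ss <- site_sets[[nm]]
    n_hit <- if (nrow(ss) == 0) 0L else {
      mid <- interval_midpoint(ss$start, ss$end)
      mid_gr <- GenomicRanges::GRanges(
        seqnames = ss$chrom,
        ranges = IRanges::IRanges(start = mid + 1, width = 1))
      sum(IRanges::overlapsAny(tss_gr, mid_gr))
    }
    data.frame(set = nm, n_genes = nrow(genes), n_hit = n_hit,
               pct = 100 * n_hit / nrow(genes), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
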