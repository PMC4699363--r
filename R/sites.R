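#' Library size factors from count totals
#'
#' Each library's factor is its total count divided by the geometric mean
#' of all totals, so multiplying a library's expected rate by its factor
#' equalizes null regions across libraries.
#'
#' @param counts matrix/data.frame of counts (regions x libraries) or a
#'   numeric vector of library totals.
#' @return numeric vector of scaling factors, one per library.
#' @examples
#' size_factors(c(100, 200))  # 1/sqrt(2), sqrt(2)
#' @export
size_factors <- function(counts) {
  totals <- if (is.matrix(counts) || is.data.frame(counts))
    colSums(as.matrix(counts)) else counts
  if (any(totals <= 0)) {
    bad <- which(totals <= 0)
    nm <- if (!is.null(names(totals))) names(totals)[bad] else bad
    stop("library with zero total count: ", paste(nm, collapse = ", "))
  }
  totals / exp(mean(log(totals)))
}

#' Pooled conditional count test for one region
#'
#' Replicate counts are pooled per condition; conditional on the total
#' `n = sum(wt) + sum(tko)`, the TKO total is Binomial(n, p0) under the
#' null, with `p0` the TKO share of the summed size factors. The two-sided
#' p-value is exact; the log2 fold change is computed on size-factor-
#' normalized totals with a 0.5 pseudocount.
#'
#' @param counts_wt,counts_tko replicate counts for one region.
#' @param factors_wt,factors_tko per-library size factors (default 1s).
#' @return list with `lfc`, `p`, `n`; `p = NA` when `n = 0` (no-test
#'   sentinel).
#' @examples
#' test_region(c(25, 25), c(30, 20))$p  # 1
#' @export
test_region <- function(counts_wt, counts_tko,
                        factors_wt = rep(1, length(counts_wt)),
                        factors_tko = rep(1, length(counts_tko))) {
  res <- test_regions(matrix(counts_wt, nrow = 1),
                      matrix(counts_tko, nrow = 1),
                      factors_wt, factors_tko)
  list(lfc = res$lfc, p = res$p, n = res$n)
}

#' Vectorized pooled conditional count test
#'
#' @param mat_wt,mat_tko matrices of counts (regions x replicates).
#' @param factors_wt,factors_tko per-library size factors.
#' @return data.frame with `lfc`, `p`, `n` per region.
#' @export
test_regions <- function(mat_wt, mat_tko,
                         factors_wt = rep(1, ncol(mat_wt)),
                         factors_tko = rep(1, ncol(mat_tko))) {
  mat_wt <- as.matrix(mat_wt); mat_tko <- as.matrix(mat_tko)
  sw <- rowSums(mat_wt); st <- rowSums(mat_tko)
  fw <- sum(factors_wt); ft <- sum(factors_tko)
  n <- sw + st
  p0 <- ft / (fw + ft)
  lower <- stats::pbinom(st, n, p0)
  upper <- stats::pbinom(st - 1, n, p0, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lower, upper))
  p[n == 0] <- NA_real_
  lfc <- log2((st / ft + 0.5) / (sw / fw + 0.5))
  data.frame(lfc = lfc, p = p, n = n)
}

#' Label regions as gained, lost or unchanged
#'
#' In `"dhs"` mode, Benjamini-Hochberg q-values are computed and regions
#' with `q < q_threshold` are labelled by the sign of the fold change
#' (false-discovery-rate control, default 5%). In `"chip"` mode, raw
#' p-value thresholding is used (default `p < 0.001`), mirroring window-
#' based differential ChIP callers.
#'
#' @param table data.frame with columns `p` and `lfc`.
#' @param mode `"dhs"` (BH FDR) or `"chip"` (raw p).
#' @param q_threshold FDR threshold for dhs mode (default 0.05).
#' @param p_threshold raw p threshold for chip mode (default 0.001).
#' @return the table with added `q` and `label` columns.
#' @export
call_changes <- function(table, mode = c("dhs", "chip"),
                         q_threshold = 0.05, p_threshold = 0.001) {
  mode <- match.arg(mode)
  if (!all(c("p", "lfc") %in% names(table)))
    stop("table must have columns p and lfc")
  table$q <- stats::p.adjust(table$p, method = "BH")
  sig <- if (mode == "dhs") !is.na(table$q) & table$q < q_threshold
         else !is.na(table$p) & table$p < p_threshold
  table$label <- "none"
  table$label[sig & table$lfc > 0] <- "gain"
  table$label[sig & table$lfc < 0] <- "loss"
  table
}

# max normalized WT signal of `signal_df` overlapping each region; 0 where
# nothing overlaps
region_signal <- function(regions, signal_df, value_col = "signal") {
  hits <- GenomicRanges::findOverlaps(as_gr(regions), as_gr(signal_df))
  out <- rep(0, nrow(regions))
  if (length(hits)) {
    agg <- tapply(signal_df[[value_col]][S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), max)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

#' Call de novo DNase hypersensitive sites
#'
#' De novo DHSs are regions called hypersensitive only in TKO cells that
#' also lack threshold H3K4me1 and H3K4me3 signal in wild-type cells --
#' i.e. sites that were not "bookmarked" by active marks before H1
#' depletion. The signal threshold is the `wt_quantile` quantile of WT
#' signal over WT-called peaks of the respective mark.
#'
#' @param tko_calls,wt_calls data.frames of called intervals (`chrom`,
#'   `start`, `end`) per condition.
#' @param k4me1_wt,k4me3_wt data.frames with `chrom`, `start`, `end`,
#'   `signal` (normalized WT coverage) and logical `called` (WT peak set
#'   defining the threshold reference).
#' @param wt_quantile quantile of WT called-peak signal used as threshold
#'   (default 0.25).
#' @return the subset of `tko_calls` that is de novo.
#' @export
call_denovo_dhs <- function(tko_calls, wt_calls, k4me1_wt, k4me3_wt,
                            wt_quantile = 0.25) {
  if (is.null(k4me1_wt) || is.null(k4me3_wt))
    stop("WT H3K4me1/H3K4me3 signal tracks are required")
  exclusive <- !IRanges::overlapsAny(as_gr(tko_calls), as_gr(wt_calls))
  cand <- tko_calls[exclusive, , drop = FALSE]
  if (nrow(cand) == 0) return(cand)
  thr1 <- stats::quantile(k4me1_wt$signal[k4me1_wt$called], wt_quantile,
                          names = FALSE)
  thr3 <- stats::quantile(k4me3_wt$signal[k4me3_wt$called], wt_quantile,
                          names = FALSE)
  s1 <- region_signal(cand, k4me1_wt)
  s3 <- region_signal(cand, k4me3_wt)
  cand[s1 < thr1 & s3 < thr3, , drop = FALSE]
}

#' Call de novo H3K4me1 sites
#'
#' Regions scoring positive for H3K4me1 only in TKO cells that also lack
#' significant H3K4me3 and DHS signal in wild-type cells.
#'
#' @param tko_calls,wt_calls H3K4me1 called intervals per condition.
#' @param k4me3_wt,dhs_wt WT signal tracks (`chrom`, `start`, `end`,
#'   `signal`, `called`).
#' @param wt_quantile threshold quantile (default 0.25).
#' @return the subset of `tko_calls` that is de novo.
#' @export
call_denovo_k4me1 <- function(tko_calls, wt_calls, k4me3_wt, dhs_wt,
                              wt_quantile = 0.25) {
  if (is.null(k4me3_wt) || is.null(dhs_wt))
    stop("WT H3K4me3/DHS signal tracks are required")
  exclusive <- !IRanges::overlapsAny(as_gr(tko_calls), as_gr(wt_calls))
  cand <- tko_calls[exclusive, , drop = FALSE]
  if (nrow(cand) == 0) return(cand)
  thr3 <- stats::quantile(k4me3_wt$signal[k4me3_wt$called], wt_quantile,
                          names = FALSE)
  thrd <- stats::quantile(dhs_wt$signal[dhs_wt$called], wt_quantile,
                          names = FALSE)
  s3 <- region_signal(cand, k4me3_wt)
  sd_ <- region_signal(cand, dhs_wt)
  cand[s3 < thr3 & sd_ < thrd, , drop = FALSE]
}

#' Hypergeometric overlap test of two interval sets within a universe
#'
#' Membership is by >= 1 bp overlap with universe regions. Drawing |A|
#' universe regions with |B| marked as successes, the p-value is the
#' upper-tail probability of observing at least the actual number of
#' regions hit by both sets; fold enrichment is observed over expected
#' overlap.
#'
#' @param a,b,universe data.frames of intervals (`chrom`, `start`, `end`).
#' @return object of class `overlap_result`: list with `n_a`, `n_b`,
#'   `n_overlap`, `universe`, `p`, `fold`.
#' @export
overlap_test <- function(a, b, universe) {
  u_gr <- as_gr(universe)
  mem <- function(x, nm) {
    gr <- as_gr(x)
    if (!all(IRanges::overlapsAny(gr, u_gr)))
      stop(nm, " contains regions outside the universe")
    unique(S4Vectors::subjectHits(GenomicRanges::findOverlaps(gr, u_gr)))
  }
  ua <- mem(a, "A"); ub <- mem(b, "B")
  n_u <- nrow(universe)
  k <- length(intersect(ua, ub))
  p <- stats::phyper(k - 1, length(ub), n_u - length(ub), length(ua),
                     lower.tail = FALSE)
  expected <- length(ua) * length(ub) / n_u
  structure(list(n_a = length(ua), n_b = length(ub), n_overlap = k,
                 universe = n_u, p = p,
                 fold = if (expected > 0) k / expected else NA_real_),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Overlap: ", x$n_overlap, " of |A|=", x$n_a, ", |B|=", x$n_b,
      " in universe ", x$universe, "; fold ", round(x$fold, 2),
      ", hypergeometric p = ", format(x$p), "\n", sep = "")
  invisible(x)
}

#' Cross-mark concordance of differential calls
#'
#' For regions significant in both of two labelled tables (matched by a
#' shared region identifier), cross-tabulates gain/loss labels and
#' computes the Spearman correlation of the paired log2 fold changes.
#'
#' @param table_a,table_b labelled tables (from [call_changes()]) sharing
#'   a `by` column.
#' @param by name of the region identifier column (default `"region_id"`).
#' @return list with `table` (2x2 gain/loss cross-table), `spearman`,
#'   `pairs` (data.frame of paired lfc values), `n`. When no region is
#'   significant in both, an empty-result sentinel with `n = 0`.
#' @export
concordance <- function(table_a, table_b, by = "region_id") {
  m <- match(table_a[[by]], table_b[[by]])
  ok <- !is.na(m) & table_a$label != "none" &
    table_b$label[m] != "none"
  if (!any(ok)) {
    empty <- matrix(0L, 2, 2,
                    dimnames = list(a = c("gain", "loss"),
                                    b = c("gain", "loss")))
    return(list(table = empty, spearman = NA_real_,
                pairs = data.frame(lfc_a = numeric(0), lfc_b = numeric(0)),
                n = 0L))
  }
  la <- factor(table_a$label[ok], levels = c("gain", "loss"))
  lb <- factor(table_b$label[m][ok], levels = c("gain", "loss"))
  pairs <- data.frame(lfc_a = table_a$lfc[ok], lfc_b = table_b$lfc[m][ok])
  rho <- if (nrow(pairs) >= 3)
    stats::cor(pairs$lfc_a, pairs$lfc_b, method = "spearman")
  else NA_real_
  list(table = table(a = la, b = lb), spearman = rho, pairs = pairs,
       n = sum(ok))
}
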