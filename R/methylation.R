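#' HpaII/MspI methylation score
#'
#' Angle-based methylation score on the 0-100 scale from paired
#' methylation-sensitive (HpaII) and methylation-insensitive (MspI)
#' restriction counts. HpaII cuts only unmethylated sites, so the score is
#' monotonically decreasing in the (depth-normalized) HpaII count:
#' `score = 100 * (1 - (2/pi) * atan2(hpa / hpa_factor, msp / msp_factor))`.
#' A site with no HpaII signal scores 100 (fully methylated); a site with
#' HpaII but no MspI signal scores 0. Sites with zero counts in both
#' digests are unassayable and return `NA`.
#'
#' @param hpa,msp non-negative counts (vectorized).
#' @param hpa_factor,msp_factor library depth factors used to normalize the
#'   two digests (defaults 1, i.e. equal depth).
#' @return numeric vector of scores in `[0, 100]`, `NA` where unassayable.
#' @examples
#' methylation_score(0, 50)   # 100
#' methylation_score(50, 0)   # 0
#' methylation_score(10, 10)  # 50
#' @export
methylation_score <- function(hpa, msp, hpa_factor = 1, msp_factor = 1) {
  if (any(hpa < 0, na.rm = TRUE) || any(msp < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  out <- 100 * (1 - (2 / pi) * atan2(hpa / hpa_factor, msp / msp_factor))
  out[hpa == 0 & msp == 0] <- NA_real_
  out
}

#' Exact binomial test for differential methylation
#'
#' Conditional on the total HpaII count of a site across the two
#' conditions, the TKO HpaII count is Binomial(n, p0) under the null of no
#' methylation difference, where p0 is the TKO share of sequencing depth.
#' The two-sided p-value is `min(1, 2 * min(lower tail, upper tail))`.
#' Excess HpaII in TKO means less methylation (hypomethylation).
#'
#' @param hpa_wt,hpa_tko HpaII counts per condition (vectorized).
#' @param depth length-2 numeric `(WT, TKO)` of library depth factors; the
#'   null probability is `depth[2] / sum(depth)`.
#' @param p_threshold significance threshold for calling a direction
#'   (default 1e-6).
#' @return data.frame with columns `p` and `direction`
#'   (`"hypo"`/`"hyper"`/`"none"`); sites with zero total HpaII get
#'   `p = NA`, `direction = "none"` (no-test sentinel).
#' @examples
#' test_differential_methylation(5, 5)         # p = 1
#' test_differential_methylation(0, 30)        # hypo, p = 2 * 0.5^30
#' @export
test_differential_methylation <- function(hpa_wt, hpa_tko,
                                          depth = c(1, 1),
                                          p_threshold = 1e-6) {
  stopifnot(length(depth) == 2, all(depth > 0))
  x <- hpa_tko
  n <- hpa_wt + hpa_tko
  p0 <- depth[2] / sum(depth)
  lower <- stats::pbinom(x, n, p0)
  upper <- stats::pbinom(x - 1, n, p0, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lower, upper))
  p[n == 0] <- NA_real_
  direction <- rep("none", length(p))
  sig <- !is.na(p) & p < p_threshold
  direction[sig & x / n > p0] <- "hypo"
  direction[sig & x / n < p0] <- "hyper"
  data.frame(p = p, direction = direction, stringsAsFactors = FALSE)
}

#' Differential methylation analysis of a site count table
#'
#' Computes per-condition methylation scores, the exact binomial test, the
#' direction call and the stringent flag for a wide methylation count
#' table (as produced by [simulate_methylation()] or read from a count
#' file with the same columns).
#'
#' @param table data.frame with columns `hpa_wt`, `msp_wt`, `hpa_tko`,
#'   `msp_tko` (other columns are carried through).
#' @param depth length-2 depth factors `(WT, TKO)`; default estimated from
#'   total HpaII library sizes.
#' @param p_threshold significance threshold (default 1e-6).
#' @param delta_threshold minimum absolute score difference for the
#'   stringent set (default 25 score units).
#' @return the input table with added columns `score_wt`, `score_tko`,
#'   `p`, `direction`, `stringent`.
#' @export
meth_diff <- function(table, depth = NULL, p_threshold = 1e-6,
                      delta_threshold = 25) {
  need <- c("hpa_wt", "msp_wt", "hpa_tko", "msp_tko")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  if (is.null(depth))
    depth <- c(sum(table$hpa_wt), sum(table$hpa_tko))
  msp_depth <- c(sum(table$msp_wt), sum(table$msp_tko))
  # each digest library normalized by its own total (CPM-like), so the
  # score compares HpaII and MspI signal on a common per-library scale
  scale <- mean(c(depth, msp_depth))
  table$score_wt <- methylation_score(table$hpa_wt, table$msp_wt,
                                      depth[1] / scale,
                                      msp_depth[1] / scale)
  table$score_tko <- methylation_score(table$hpa_tko, table$msp_tko,
                                       depth[2] / scale,
                                       msp_depth[2] / scale)
  res <- test_differential_methylation(table$hpa_wt, table$hpa_tko,
                                       depth, p_threshold)
  table$p <- res$p
  table$direction <- res$direction
  classify_stringent(table, delta_threshold = delta_threshold,
                     p_threshold = p_threshold)
}

#' Flag stringent differentially methylated sites
#'
#' A site is stringent when its binomial p-value is below `p_threshold`
#' and the absolute score difference between conditions is at least
#' `delta_threshold` score units.
#'
#' @param table data.frame with columns `p`, `score_wt`, `score_tko`.
#' @param delta_threshold minimum |score_TKO - score_WT| (default 25).
#' @param p_threshold significance threshold (default 1e-6).
#' @return the table with a logical `stringent` column.
#' @export
classify_stringent <- function(table, delta_threshold = 25,
                               p_threshold = 1e-6) {
  need <- c("p", "score_wt", "score_tko")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  delta <- abs(table$score_tko - table$score_wt)
  table$stringent <- !is.na(table$p) & table$p < p_threshold &
    !is.na(delta) & delta >= delta_threshold
  table
}

#' Permutation test for spatial clustering of differential sites
#'
#' Tiles each chromosome with fixed non-overlapping windows anchored at
#' coordinate 0 and counts windows containing at least `min_sites`
#' differential sites. The null distribution is obtained by repeatedly
#' drawing the same number of sites uniformly (without replacement) from
#' the full assayable set and recounting. The empirical p-value is
#' `(1 + #(null >= observed)) / (draws + 1)`.
#'
#' @param dmr_sites,assayable_sites data.frames with `chrom`, `start`,
#'   `end`; `assayable_sites` is the universe the differential sites were
#'   drawn from.
#' @param window window size in bp (default 20000).
#' @param min_sites minimum sites per qualifying window (default 5).
#' @param draws number of null draws (default 1000).
#' @param seed RNG seed for the draws (required for reproducibility).
#' @return object of class `window_cluster_result`: list with `observed`,
#'   `null_counts`, `draws`, `window`, `min_sites`, `p`.
#' @export
window_cluster_test <- function(dmr_sites, assayable_sites,
                                window = 20000, min_sites = 5,
                                draws = 1000, seed) {
  if (window <= 0) stop("window must be positive")
  m <- nrow(dmr_sites)
  n <- nrow(assayable_sites)
  if (m > n) stop("more differential sites than assayable sites")
  count_windows <- function(wid) {
    if (length(wid) == 0) return(0L)
    sum(table(wid) >= min_sites)
  }
  wid_of <- function(df)
    paste(df$chrom, interval_midpoint(df$start, df$end) %/% window)
  observed <- count_windows(wid_of(dmr_sites))
  # canonical genomic order, so the null draws (hence p) do not depend on
  # the row or chromosome ordering of the input
  o <- order(assayable_sites$chrom, assayable_sites$start,
             assayable_sites$end)
  all_wid <- wid_of(assayable_sites[o, , drop = FALSE])
  # integer window codes for fast tabulation in the null loop
  codes <- match(all_wid, unique(all_wid))
  nw <- max(codes)
  null_counts <- withr::with_seed(seed, {
    vapply(seq_len(draws), function(i) {
      cnt <- tabulate(codes[sample.int(n, m)], nbins = nw)
      sum(cnt >= min_sites)
    }, integer(1))
  })
  p <- (1 + sum(null_counts >= observed)) / (draws + 1)
  structure(list(observed = observed, null_counts = null_counts,
                 draws = draws, window = window, min_sites = min_sites,
                 p = p),
            class = "window_cluster_result")
}

#' @export
print.window_cluster_result <- function(x, ...) {
  cat("Window clustering test: ", x$observed, " windows (", x$window,
      " bp, >= ", x$min_sites, " sites); null mean ",
      round(mean(x$null_counts), 2), " over ", x$draws,
      " draws; empirical p = ", format(x$p), "\n", sep = "")
  invisible(x)
}

#' Chromatin-state composition of a site set
#'
#' Assigns each site to the chromatin state at its interval midpoint and
#' returns the fraction of sites per state, together with the same
#' composition for a size-matched random draw from the assayable set (the
#' random-selection baseline). Sites falling outside the segmentation are
#' counted under `"other"` with a warning.
#'
#' @param sites data.frame with `chrom`, `start`, `end`; must be non-empty.
#' @param states segmentation data.frame with `chrom`, `start`, `end`,
#'   `state`.
#' @param assayable optional data.frame of assayable sites for the matched
#'   random baseline.
#' @param seed RNG seed for the baseline draw.
#' @return data.frame with `state`, `fraction` and (when `assayable` is
#'   given) `baseline_fraction`; fractions sum to 1.
#' @export
state_composition <- function(sites, states, assayable = NULL, seed = 1) {
  if (nrow(sites) == 0) stop("empty site list")
  labels <- sort(unique(states$state))
  if (!"other" %in% labels) labels <- c(labels, "other")
  assign_states <- function(df, warn = TRUE) {
    idx <- midpoint_assign(df, states)
    if (warn && anyNA(idx))
      warning(sum(is.na(idx)), " site(s) outside the segmentation span; ",
              "counted as 'other'")
    st <- ifelse(is.na(idx), "other", states$state[idx])
    factor(st, levels = labels)
  }
  frac <- table(assign_states(sites)) / nrow(sites)
  out <- data.frame(state = labels, fraction = as.numeric(frac),
                    stringsAsFactors = FALSE)
  if (!is.null(assayable)) {
    draw <- withr::with_seed(seed,
      assayable[sample.int(nrow(assayable), min(nrow(sites),
                                                nrow(assayable))), ])
    bfrac <- table(assign_states(draw, warn = FALSE)) / nrow(draw)
    out$baseline_fraction <- as.numeric(bfrac)
  }
  out
}
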