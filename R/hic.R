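#' Contact matrix container
#'
#' A per-chromosome symmetric matrix of binned contact values at a fixed
#' bin size, with a usable-bin mask and a raw/balanced flag.
#'
#' @param mat symmetric numeric matrix of non-negative values.
#' @param chrom chromosome name.
#' @param bin_size bin size in bp.
#' @param balanced logical; has the matrix been balanced?
#' @param mask logical vector, `TRUE` = usable bin (default all usable).
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(mat, chrom, bin_size, balanced = FALSE,
                           mask = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("contact matrix must be square")
  if (max(abs(mat - t(mat))) > 1e-9) stop("contact matrix must be symmetric")
  if (any(mat < 0)) stop("contact values must be non-negative")
  if (is.null(mask)) mask <- rep(TRUE, nrow(mat))
  structure(list(chrom = chrom, bin_size = bin_size, mat = mat,
                 balanced = balanced, mask = mask),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("Contact matrix ", x$chrom, ": ", nrow(x$mat), " bins of ",
      x$bin_size / 1e3, " kb (", if (x$balanced) "balanced" else "raw",
      "), ", sum(!x$mask), " masked, total ",
      round(sum(x$mat[upper.tri(x$mat, diag = TRUE)])), "\n", sep = "")
  invisible(x)
}

#' Bin contact pairs or COO triples into contact matrices
#'
#' Accepts either a valid-pair table (`chrom1`, `pos1`, `chrom2`, `pos2`)
#' or pre-binned COO triples (`chrom`, `bin1`, `bin2`, `count`; cis only).
#' Each intra-chromosomal pair is accumulated once into cells (i, j) and
#' (j, i); inter-chromosomal pairs contribute only to the cis fraction
#' statistic.
#'
#' @param pairs data.frame in one of the two schemas above.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bin_size bin size in bp (default 100 kb).
#' @return list with `matrices` (named list of [contact_matrix()]) and
#'   `cis_fraction` (fraction of intra-chromosomal pairs; `NA` for COO
#'   input, which is cis by construction).
#' @export
bin_contacts <- function(pairs, chrom_lengths, bin_size = 100000) {
  n_bins <- setNames(as.integer(ceiling(chrom_lengths / bin_size)),
                     names(chrom_lengths))
  empty <- lapply(n_bins, function(nb) matrix(0, nb, nb))
  if (all(c("chrom", "bin1", "bin2", "count") %in% names(pairs))) {
    bad <- !pairs$chrom %in% names(chrom_lengths)
    if (any(bad))
      stop("unknown chromosome in row ", which(bad)[1], ": ",
           pairs$chrom[which(bad)[1]])
    oob <- pairs$bin1 >= n_bins[pairs$chrom] |
      pairs$bin2 >= n_bins[pairs$chrom] | pairs$bin1 < 0 | pairs$bin2 < 0
    if (any(oob)) stop("bin index out of range in row ", which(oob)[1])
    for (cn in unique(pairs$chrom)) {
      pp <- pairs[pairs$chrom == cn, ]
      m <- empty[[cn]]
      for (k in seq_len(nrow(pp))) {
        i <- pp$bin1[k] + 1L; j <- pp$bin2[k] + 1L
        m[i, j] <- m[i, j] + pp$count[k]
        if (i != j) m[j, i] <- m[j, i] + pp$count[k]
      }
      empty[[cn]] <- m
    }
    cis_fraction <- NA_real_
  } else if (all(c("chrom1", "pos1", "chrom2", "pos2") %in% names(pairs))) {
    bad <- !(pairs$chrom1 %in% names(chrom_lengths)) |
      !(pairs$chrom2 %in% names(chrom_lengths))
    if (any(bad)) stop("unknown chromosome in row ", which(bad)[1])
    cis <- pairs$chrom1 == pairs$chrom2
    cis_fraction <- mean(cis)
    pp <- pairs[cis, ]
    b1 <- as.integer(pp$pos1 %/% bin_size)
    b2 <- as.integer(pp$pos2 %/% bin_size)
    oob <- b1 >= n_bins[pp$chrom1] | b2 >= n_bins[pp$chrom1] |
      pp$pos1 < 0 | pp$pos2 < 0
    if (any(oob)) stop("position out of chromosome bounds in row ",
                       which(oob)[1])
    for (cn in unique(pp$chrom1)) {
      sel <- pp$chrom1 == cn
      m <- empty[[cn]]
      for (k in which(sel)) {
        i <- b1[k] + 1L; j <- b2[k] + 1L
        m[i, j] <- m[i, j] + 1
        if (i != j) m[j, i] <- m[j, i] + 1
      }
      empty[[cn]] <- m
    }
  } else {
    stop("pairs must have columns chrom/bin1/bin2/count or ",
         "chrom1/pos1/chrom2/pos2")
  }
  mats <- lapply(names(empty), function(cn)
    contact_matrix(empty[[cn]], chrom = cn, bin_size = bin_size))
  names(mats) <- names(empty)
  list(matrices = mats, cis_fraction = cis_fraction)
}

#' Balance a contact matrix by iterative proportional fitting
#'
#' Low-coverage bins (row sum below `mask_frac` of the median positive row
#' sum) are masked, then the unmasked submatrix is scaled iteratively
#' (Sinkhorn-Knopp on a symmetric matrix) until every unmasked row sum is
#' within `tol` of their common mean.
#'
#' @param cm a raw [contact_matrix()].
#' @param max_iter maximum iterations (default 200).
#' @param tol relative row-sum tolerance (default 1e-6).
#' @param mask_frac low-coverage mask threshold (default 0.1).
#' @return a balanced `contact_matrix`; masked rows/columns are zero.
#' @export
balance <- function(cm, max_iter = 200, tol = 1e-6, mask_frac = 0.1) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (cm$balanced) stop("matrix is already balanced")
  rs <- rowSums(cm$mat)
  med <- stats::median(rs[rs > 0])
  mask <- rs >= mask_frac * med
  b <- cm$mat[mask, mask, drop = FALSE]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- rowSums(b)
    if (any(s == 0)) stop("empty row inside unmasked submatrix")
    r <- s / mean(s)
    if (max(abs(r - 1)) < tol) { converged <- TRUE; break }
    b <- b / sqrt(outer(r, r))
  }
  if (!converged)
    stop("balancing did not converge in ", max_iter,
         " iterations; residual ", format(max(abs(rowSums(b) /
                                                  mean(rowSums(b)) - 1))))
  out <- matrix(0, nrow(cm$mat), ncol(cm$mat))
  out[mask, mask] <- b
  out <- (out + t(out)) / 2  # enforce exact symmetry
  contact_matrix(out, chrom = cm$chrom, bin_size = cm$bin_size,
                 balanced = TRUE, mask = mask)
}

#' Mean contact by genomic distance and the contact-fraction decay curve
#'
#' @param cm a [contact_matrix()].
#' @param n_bands number of log-spaced distance bands for the fraction
#'   curve (default 15).
#' @return list with `expected` (data.frame `distance` in bins, `mean`
#'   over unmasked pairs, `n` pairs) and `fraction` (data.frame `d_min`,
#'   `d_max`, `fraction`; sums to 1 over cis contacts at distance >= 1).
#' @export
expected_by_distance <- function(cm, n_bands = 15) {
  stopifnot(inherits(cm, "contact_matrix"))
  nb <- nrow(cm$mat)
  idx <- which(cm$mask)
  m <- cm$mat[idx, idx, drop = FALSE]
  d <- abs(outer(idx, idx, "-"))
  keep <- upper.tri(d, diag = TRUE)
  dv <- d[keep]; mv <- m[keep]
  mean_by_d <- tapply(mv, dv, mean)
  n_by_d <- tapply(mv, dv, length)
  expected <- data.frame(distance = as.integer(names(mean_by_d)),
                         mean = as.numeric(mean_by_d),
                         n = as.integer(n_by_d))
  off <- dv >= 1
  total <- sum(mv[off])
  edges <- unique(round(exp(seq(0, log(nb), length.out = n_bands + 1))))
  frac <- vapply(seq_len(length(edges) - 1), function(k)
    sum(mv[off & dv >= edges[k] & dv < edges[k + 1]]) / total, numeric(1))
  fraction <- data.frame(d_min = edges[-length(edges)],
                         d_max = edges[-1], fraction = frac)
  list(expected = expected, fraction = fraction)
}

#' Fit the contact distance-decay exponent
#'
#' Log-log regression of mean contact on bin distance over a distance
#' range; returns the negated slope, so a value of 1 means contacts fall
#' off as 1/d.
#'
#' @param cm a [contact_matrix()].
#' @param d_range distance range in bins used for the fit (default 2-50).
#' @return fitted exponent (positive for decaying contacts).
#' @export
fit_decay_exponent <- function(cm, d_range = c(2, 50)) {
  e <- expected_by_distance(cm)$expected
  e <- e[e$distance >= d_range[1] & e$distance <= d_range[2] & e$mean > 0, ]
  if (nrow(e) < 3) stop("too few distance bins in range for a fit")
  -unname(stats::coef(stats::lm(log(mean) ~ log(distance), data = e))[2])
}

#' A/B compartment eigenvector of a contact matrix
#'
#' Computes the observed/expected matrix (each cell divided by the mean
#' contact at its distance), its Pearson correlation matrix, and the first
#' principal component. The sign is oriented so the eigenvector correlates
#' positively with gene density; bins with positive coefficients are
#' labelled "A", negative "B". Masked bins are `NA`.
#'
#' @param cm a [contact_matrix()] (balanced recommended).
#' @param gene_density numeric vector (one value per bin) used to orient
#'   the sign; typically gene or active-mark counts per bin.
#' @return data.frame with `bin` (0-based), `pc1`, `compartment`.
#' @export
compartment_pc1 <- function(cm, gene_density) {
  stopifnot(inherits(cm, "contact_matrix"))
  nb <- nrow(cm$mat)
  if (length(gene_density) != nb)
    stop("gene_density must have one value per bin")
  idx <- which(cm$mask)
  if (length(idx) < 20) stop("need at least 20 unmasked bins")
  m <- cm$mat[idx, idx, drop = FALSE]
  d <- abs(outer(idx, idx, "-"))
  exp_d <- tapply(m, d, mean)
  oe <- m / matrix(exp_d[as.character(d)], nrow(m))
  oe[!is.finite(oe)] <- 0
  if (any(apply(oe, 2, stats::sd) == 0))
    stop("degenerate observed/expected matrix: zero-variance bin")
  cc <- stats::cor(oe)
  ev <- eigen(cc, symmetric = TRUE)
  pc1 <- ev$vectors[, 1]
  gd <- gene_density[idx]
  if (stats::sd(gd) > 0 && stats::cor(pc1, gd) < 0) pc1 <- -pc1
  out <- data.frame(bin = seq_len(nb) - 1L, pc1 = NA_real_,
                    compartment = NA_character_,
                    stringsAsFactors = FALSE)
  out$pc1[idx] <- pc1
  out$compartment[idx] <- ifelse(pc1 > 0, "A", "B")
  out
}

#' Paired-anchor aggregate Hi-C analysis (PE-SCAN)
#'
#' For every intra-chromosomal pair of anchor loci within a distance
#' range, extracts the `(2*flank+1)^2` observed/expected window centered
#' on the pair and averages across pairs. The center enrichment is the
#' center cell over the mean of the window's border cells; preferential
#' spatial clustering of the anchors shows as center enrichment above 1.
#'
#' @param cm a [contact_matrix()].
#' @param anchor_bins 0-based bin indices of the anchors (>= 2).
#' @param flank flank in bins around each anchor (default 5).
#' @param d_range anchor-pair distance range in bp (default 2-50 Mb).
#' @return list with `aggregate` (the averaged window),
#'   `center_enrichment` and `n_pairs`; when no pair is eligible, a
#'   sentinel with `n_pairs = 0` and `NA` enrichment.
#' @export
pe_scan <- function(cm, anchor_bins, flank = 5, d_range = c(2e6, 5e7)) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (length(anchor_bins) < 2) stop("need at least 2 anchors")
  nb <- nrow(cm$mat)
  idx_all <- seq_len(nb)
  d <- abs(outer(idx_all, idx_all, "-"))
  exp_d <- tapply(cm$mat, d, mean)
  oe <- cm$mat / matrix(exp_d[as.character(d)], nb)
  oe[!is.finite(oe)] <- 0
  w <- 2L * flank + 1L
  a <- sort(unique(as.integer(anchor_bins))) + 1L
  lo <- d_range[1] / cm$bin_size
  hi <- d_range[2] / cm$bin_size
  agg <- matrix(0, w, w)
  n_pairs <- 0L
  for (x in seq_along(a)) for (y in seq_along(a)) {
    if (y <= x) next
    i <- a[x]; j <- a[y]
    dd <- abs(i - j)
    if (dd < max(lo, 2 * flank + 1) || dd > hi) next
    if (i - flank < 1 || i + flank > nb || j - flank < 1 || j + flank > nb)
      next
    agg <- agg + oe[(i - flank):(i + flank), (j - flank):(j + flank)]
    n_pairs <- n_pairs + 1L
  }
  if (n_pairs == 0)
    return(list(aggregate = NULL, center_enrichment = NA_real_,
                n_pairs = 0L))
  agg <- agg / n_pairs
  center <- agg[flank + 1L, flank + 1L]
  border <- c(agg[1, ], agg[w, ], agg[-c(1, w), 1], agg[-c(1, w), w])
  list(aggregate = agg, center_enrichment = center / mean(border),
       n_pairs = n_pairs)
}

#' Per-TAD domain score (cross-boundary ratio)
#'
#' The domain score of a TAD divides its intra-domain contacts (upper
#' triangle including the diagonal over the TAD's bins) by its inter-
#' domain contacts (cells with exactly one end in the TAD and the other
#' anywhere else on the same chromosome), with a pseudocount keeping
#' fully insulated TADs finite. TADs spanning fewer than two complete
#' bins are skipped with a warning.
#'
#' @param cm a [contact_matrix()].
#' @param tads data.frame with `chrom`, `start`, `end`, `tad_id`; only
#'   rows on `cm$chrom` are scored.
#' @param pseudocount added to both sums (default 1).
#' @param condition optional label stored in the result.
#' @return data.frame with `tad_id`, `intra`, `inter`, `score`,
#'   `condition`.
#' @export
domain_score <- function(cm, tads, pseudocount = 1, condition = NA) {
  stopifnot(inherits(cm, "contact_matrix"))
  bs <- cm$bin_size
  nb <- nrow(cm$mat)
  tt <- tads[tads$chrom == cm$chrom, , drop = FALSE]
  rows <- list()
  skipped <- 0L
  for (k in seq_len(nrow(tt))) {
    b0 <- ceiling(tt$start[k] / bs)        # first bin fully inside
    b1 <- floor(tt$end[k] / bs) - 1        # last bin fully inside
    if (b1 < b0 + 1 || b0 < 0 || b1 >= nb) { skipped <- skipped + 1L; next }
    sel <- (b0:b1) + 1L
    sub <- cm$mat[sel, sel, drop = FALSE]
    intra <- sum(sub[upper.tri(sub, diag = TRUE)])
    inter <- sum(cm$mat[sel, , drop = FALSE]) - sum(sub)
    rows[[length(rows) + 1L]] <- data.frame(
      tad_id = tt$tad_id[k], intra = intra, inter = inter,
      score = (intra + pseudocount) / (inter + pseudocount),
      condition = condition, stringsAsFactors = FALSE)
  }
  if (skipped > 0)
    warning(skipped, " TAD(s) smaller than two bins skipped on ", cm$chrom)
  if (length(rows) == 0)
    return(data.frame(tad_id = character(0), intra = numeric(0),
                      inter = numeric(0), score = numeric(0),
                      condition = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Compare per-TAD domain scores between conditions
#'
#' Per-TAD score difference (TKO - WT) plus a two-sided two-sample
#' Wilcoxon rank-sum test comparing the score distributions, as used to
#' test the genome-wide shift toward lower domain scores after H1
#' depletion.
#'
#' @param records_wt,records_tko [domain_score()] outputs over the same
#'   TAD set.
#' @return list with `deltas` (data.frame `tad_id`, `score_wt`,
#'   `score_tko`, `delta`), `p`, `statistic`, `frac_negative` (fraction
#'   of TADs with lower score in TKO).
#' @export
compare_domain_scores <- function(records_wt, records_tko) {
  if (!setequal(records_wt$tad_id, records_tko$tad_id)) {
    d1 <- setdiff(records_wt$tad_id, records_tko$tad_id)
    d2 <- setdiff(records_tko$tad_id, records_wt$tad_id)
    stop("TAD sets differ between conditions: ",
         paste(utils::head(c(d1, d2), 10), collapse = ", "))
  }
  m <- match(records_wt$tad_id, records_tko$tad_id)
  deltas <- data.frame(
    tad_id = records_wt$tad_id,
    score_wt = records_wt$score,
    score_tko = records_tko$score[m],
    delta = records_tko$score[m] - records_wt$score,
    stringsAsFactors = FALSE)
  wt <- stats::wilcox.test(records_tko$score, records_wt$score,
                           exact = FALSE)
  list(deltas = deltas, p = wt$p.value,
       statistic = unname(wt$statistic),
       frac_negative = mean(deltas$delta < 0))
}

#' Quintile analysis of epigenetic changes by domain-score difference
#'
#' Ranks TADs by their domain-score difference (TKO - WT), splits them
#' into quintiles and computes the percentage of each mark's changes (and
#' of their sum) per quintile, with a chi-squared test of the summed
#' changes against an expected distribution. Additional ranking keys can
#' be supplied as negative controls (e.g. gene count, TAD size, DE-gene
#' count).
#'
#' @param deltas numeric vector of per-TAD score differences.
#' @param changes data.frame/matrix of per-TAD change counts, one column
#'   per mark (rows aligned with `deltas`).
#' @param expected_prop expected per-bin proportions for the chi-squared
#'   test (default equal across quintiles, since quintiles hold equal TAD
#'   numbers).
#' @param controls optional named list of alternative ranking keys.
#' @return list with `bins`, `pct` (data.frame bin x mark percentages,
#'   incl. `total`), `chisq` (from [chisq_nonuniformity()]), and
#'   `controls` (same summaries per control key).
#' @export
delta_score_quintiles <- function(deltas, changes,
                                  expected_prop = rep(0.2, 5),
                                  controls = NULL) {
  changes <- as.data.frame(changes)
  one <- function(key) {
    bins <- quintile_bins(key)
    total <- rowSums(changes)
    pct <- data.frame(bin = 1:5)
    for (nm in names(changes))
      pct[[nm]] <- bin_percentages(changes[[nm]], bins)$pct
    pct$total <- bin_percentages(total, bins)$pct
    obs <- vapply(1:5, function(b) sum(total[bins == b]), numeric(1))
    list(bins = bins, pct = pct,
         chisq = chisq_nonuniformity(obs, expected_prop))
  }
  main <- one(deltas)
  ctl <- if (!is.null(controls)) lapply(controls, one) else NULL
  c(main, list(controls = ctl))
}
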