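# Contact matrices: binning, balancing, compartments, decay, PE-SCAN,
# domain scores.

test_that("contact binning accumulates pairs and tracks the cis fraction", {
  cl <- c(chr1 = 1e6, chr2 = 1e6)
  pairs <- data.frame(chrom1 = c("chr1", "chr1", "chr1", "chr1"),
                      pos1 = c(50e3, 150e3, 420e3, 10e3),
                      chrom2 = c("chr1", "chr1", "chr1", "chr2"),
                      pos2 = c(150e3, 160e3, 430e3, 900e3))
  r <- bin_contacts(pairs, cl, bin_size = 1e5)
  m <- r$matrices$chr1$mat
  expect_equal(m[1, 2], 1)
  expect_equal(m[2, 1], 1)
  expect_equal(m[2, 2], 1)
  expect_equal(m[5, 5], 1)
  expect_equal(r$cis_fraction, 0.75)
  # total matrix sum counts each cis pair once (off-diagonal twice mirrored)
  expect_equal(sum(m[upper.tri(m, diag = TRUE)]), 3)
  expect_error(bin_contacts(data.frame(chrom1 = "chrX", pos1 = 1,
                                       chrom2 = "chrX", pos2 = 2), cl),
               "row 1")
  # COO input path
  coo <- data.frame(chrom = "chr2", bin1 = c(0, 3), bin2 = c(3, 0),
                    count = c(2, 1))
  m2 <- bin_contacts(coo, cl, bin_size = 1e5)$matrices$chr2$mat
  expect_equal(m2[1, 4], 3)
  expect_equal(m2[4, 1], 3)
})

test_that("balancing reaches uniform row sums and matches a Sinkhorn oracle", {
  # already-uniform matrix is a fixed point
  u <- matrix(1, 10, 10)
  cu <- contact_matrix(u, "chr1", 1e5)
  bu <- balance(cu)
  expect_equal(bu$mat, u, tolerance = 1e-6)
  # random matrix: row sums equalized within tolerance
  cm <- random_contact_matrix(25, seed = 2)
  b <- balance(cm, tol = 1e-8)
  rs <- rowSums(b$mat[b$mask, b$mask])
  expect_lt(max(rs) / min(rs), 1 + 1e-6)
  expect_identical(b$mat, t(b$mat))
  # independent Sinkhorn oracle on a small symmetric matrix
  h <- matrix(c(4, 2, 1, 1,
                2, 6, 2, 1,
                1, 2, 5, 3,
                1, 1, 3, 7), 4, 4)
  got <- balance(contact_matrix(h, "c", 1), tol = 1e-12)$mat
  x <- h
  for (i in 1:10000) {
    s <- rowSums(x); x <- x / sqrt(outer(s / mean(s), s / mean(s)))
  }
  expect_equal(got / mean(got), x / mean(x), tolerance = 1e-8)
  expect_error(balance(b), "already balanced")
})

test_that("distance curves are flat for uniform input and normalized", {
  u <- contact_matrix(matrix(3, 12, 12), "chr1", 1e5)
  e <- expected_by_distance(u)
  expect_true(all(e$expected$mean == 3))
  expect_equal(sum(e$fraction$fraction), 1)
  cm <- random_contact_matrix(30, seed = 5)
  expect_equal(sum(expected_by_distance(cm)$fraction$fraction), 1)
})

test_that("compartment eigenvector recovers planted blocks and orientation", {
  p <- sim_params(seed = 25, compartment_strength = 0.5)
  g <- make_genome(p)
  h <- simulate_hic(g, condition = "WT")
  bb <- g$bins[g$bins$chrom == "chr1", ]
  gd <- tabulate(g$genes$tss[g$genes$chrom == "chr1"] %/% 1e5 + 1,
                 nbins = nrow(bb))
  b <- balance(h$chr1)
  pc <- compartment_pc1(b, gd)
  ok <- !is.na(pc$compartment)
  expect_gte(mean(pc$compartment[ok] == bb$compartment[ok]), 0.95)
  # flipping the orientation track flips labels, not |PC1|
  pc2 <- compartment_pc1(b, -gd)
  expect_equal(abs(pc2$pc1), abs(pc$pc1))
  flip <- c(A = "B", B = "A")
  expect_identical(unname(flip[pc$compartment[ok]]), pc2$compartment[ok])
  # scaling invariance (up to sign handled by orientation)
  b2 <- contact_matrix(b$mat * 7, b$chrom, b$bin_size, balanced = TRUE,
                       mask = b$mask)
  pc3 <- compartment_pc1(b2, gd)
  expect_equal(pc3$pc1, pc$pc1, tolerance = 1e-9)
  expect_error(compartment_pc1(contact_matrix(matrix(1, 10, 10), "c", 1),
                               rep(1, 10)), "20 unmasked")
})

test_that("weak compartments are not confidently recovered", {
  p <- sim_params(seed = 26, compartment_strength = 0)
  g <- make_genome(p)
  h <- simulate_hic(g, condition = "WT")
  bb <- g$bins[g$bins$chrom == "chr1", ]
  gd <- tabulate(g$genes$tss[g$genes$chrom == "chr1"] %/% 1e5 + 1,
                 nbins = nrow(bb))
  pc <- compartment_pc1(balance(h$chr1), gd)
  ok <- !is.na(pc$compartment)
  agree <- mean(pc$compartment[ok] == bb$compartment[ok])
  expect_lt(abs(agree - 0.5), 0.25)
})

test_that("PE-SCAN aggregates anchor pairs and reports center enrichment", {
  p0 <- sim_params(seed = 27, compartment_strength = 0,
                   tad_block_strength = 0)
  g0 <- make_genome(p0)
  anch <- list(chr1 = as.integer(seq(15, 235, by = 22)))
  h2 <- simulate_hic(g0, condition = "WT", anchor_bins = anch,
                     anchor_boost = 2)
  ps <- pe_scan(h2$chr1, anch$chr1)
  expect_equal(dim(ps$aggregate), c(11, 11))
  expect_gt(ps$n_pairs, 10)
  expect_lt(abs(ps$center_enrichment - 2), 0.3)
  # homogeneous matrix with random anchors: enrichment ~ 1
  h1 <- simulate_hic(g0, condition = "WT")
  ps1 <- pe_scan(h1$chr1, anch$chr1)
  expect_lt(abs(ps1$center_enrichment - 1), 0.15)
  # no eligible pairs: sentinel
  ps0 <- pe_scan(h1$chr1, c(10L, 12L))
  expect_equal(ps0$n_pairs, 0)
  expect_true(is.na(ps0$center_enrichment))
})

test_that("domain score matches closed form and brute-force oracle", {
  # uniform matrix closed form: intra = c*n(n+1)/2, inter = c*n*(N-n)
  N <- 20; cval <- 3
  u <- contact_matrix(matrix(cval, N, N), "chr1", 1e5)
  tad <- data.frame(chrom = "chr1", start = 4e5, end = 9e5, tad_id = "t")
  ds <- domain_score(u, tad)
  n <- 5
  expect_equal(ds$intra, cval * n * (n + 1) / 2)
  expect_equal(ds$inter, cval * n * (N - n))
  expect_equal(ds$score, (ds$intra + 1) / (ds$inter + 1))
  # block-diagonal: zero inter
  bm <- matrix(0, 10, 10); bm[1:3, 1:3] <- 5
  cb <- contact_matrix(bm, "chr1", 1e5)
  dsb <- domain_score(cb, data.frame(chrom = "chr1", start = 0, end = 3e5,
                                     tad_id = "b"))
  expect_equal(dsb$score, (sum(bm[1:3, 1:3][upper.tri(bm[1:3, 1:3],
                                                      diag = TRUE)]) + 1) / 1)
  # random matrices vs double-loop oracle
  withr::with_seed(31, {
    for (rep in 1:5) {
      cm <- random_contact_matrix(30, seed = rep)
      b0 <- sample(0:20, 1); width <- sample(2:8, 1)
      tadr <- data.frame(chrom = "chrX", start = b0 * 1e5,
                         end = (b0 + width) * 1e5, tad_id = "r")
      got <- domain_score(cm, tadr)
      expect_equal(got$score,
                   oracle_domain_score(cm$mat, (b0 + 1):(b0 + width)))
    }
  })
  # a TAD smaller than two bins is skipped with a warning
  expect_warning(
    none <- domain_score(u, data.frame(chrom = "chr1", start = 0, end = 1e5,
                                       tad_id = "small")),
    "skipped")
  expect_equal(nrow(none), 0)
})

test_that("domain-score comparison detects the planted TKO shift", {
  pS <- sim_params(seed = 33, altered_tad_fraction = 1)
  gS <- make_genome(pS)
  dw <- do.call(rbind, lapply(simulate_hic(gS, condition = "WT"),
                              function(cm) domain_score(balance(cm), gS$tads,
                                                        condition = "WT")))
  dt <- do.call(rbind, lapply(simulate_hic(gS, condition = "TKO"),
                              function(cm) domain_score(balance(cm), gS$tads,
                                                        condition = "TKO")))
  cmp <- compare_domain_scores(dw, dt)
  expect_lt(cmp$p, 0.01)
  expect_lt(stats::median(cmp$deltas$delta), 0)
  expect_gt(cmp$frac_negative, 0.8)
  # identical inputs: all deltas zero, p ~ 1
  same <- compare_domain_scores(dw, transform(dw, condition = "TKO"))
  expect_true(all(same$deltas$delta == 0))
  expect_gt(same$p, 0.9)
  expect_error(compare_domain_scores(dw, dt[-1, ]), "differ")
})

test_that("Wilcoxon statistic agrees with exact enumeration for small n", {
  withr::with_seed(35, {
    x <- rnorm(6); y <- rnorm(5)
    dw <- data.frame(tad_id = sprintf("t%d", 1:6), score = x,
                     condition = "WT")
    dt <- data.frame(tad_id = sprintf("t%d", 1:6),
                     score = c(y, rnorm(1)), condition = "TKO")
    got <- compare_domain_scores(dw, dt)
    # brute-force rank-sum statistic: pairs (tko_i > wt_j)
    W <- sum(outer(dt$score, dw$score, ">"))
    expect_equal(got$statistic, W)
    ref <- stats::wilcox.test(dt$score, dw$score, exact = FALSE)
    expect_equal(got$p, ref$p.value)
  })
})

test_that("delta-score quintiles report per-mark percentages that sum to 100", {
  withr::with_seed(37, {
    n <- 50
    deltas <- rnorm(n)
    changes <- data.frame(a = rpois(n, 5), b = rpois(n, 3))
    dq <- delta_score_quintiles(deltas, changes,
                                controls = list(size = runif(n)))
    expect_equal(sum(dq$pct$a), 100, tolerance = 1e-9)
    expect_equal(sum(dq$pct$b), 100, tolerance = 1e-9)
    expect_equal(sum(dq$pct$total), 100, tolerance = 1e-9)
    expect_equal(sum(dq$controls$size$pct$total), 100, tolerance = 1e-9)
    # uniform changes over equal bins: each ~20%
    flat <- delta_score_quintiles(seq_len(50), data.frame(x = rep(4, 50)))
    expect_equal(flat$pct$x, rep(20, 5))
  })
})
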