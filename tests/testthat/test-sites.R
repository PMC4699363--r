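# Differential DNase/ChIP testing, de novo definitions, overlap statistics.

test_that("size factors follow the closed form and reject empty libraries", {
  expect_equal(size_factors(c(100, 100, 100)), c(1, 1, 1))
  expect_equal(size_factors(c(100, 200)), c(1 / sqrt(2), sqrt(2)))
  expect_equal(prod(size_factors(c(3, 17, 41))), 1, tolerance = 1e-12)
  expect_error(size_factors(c(a = 10, b = 0)), "b")
})

test_that("pooled region test matches the exact binomial oracle", {
  r <- test_region(c(25, 25), c(30, 20))
  expect_equal(r$p, 1)
  expect_equal(r$lfc, 0)
  r2 <- test_region(c(0, 0), c(12, 8))
  expect_equal(r2$p, 2 * 0.5^20)
  expect_gt(r2$lfc, 0)
  expect_true(is.na(test_region(0, 0)$p))
  # oracle equivalence over random cases with unequal depth factors
  withr::with_seed(4, {
    for (i in 1:25) {
      w <- rpois(3, 40); t <- rpois(2, 60)
      fw <- runif(3, 0.5, 2); ft <- runif(2, 0.5, 2)
      got <- test_region(w, t, fw, ft)
      p0 <- sum(ft) / (sum(fw) + sum(ft))
      expect_equal(got$p, oracle_binom_p(sum(t), sum(w) + sum(t), p0),
                   tolerance = 1e-12)
    }
  })
})

test_that("region-test type-I error stays near nominal on null data", {
  withr::with_seed(99, {
    n <- 5000
    w <- matrix(rpois(n * 3, 20), n)
    t <- matrix(rpois(n * 3, 20), n)
    res <- test_regions(w, t)
    rate <- mean(res$p < 0.001)
    expect_lte(rate, 0.0015)
  })
})

test_that("BH calling labels by q-value and respects monotonicity", {
  tab <- data.frame(p = c(0.001, 0.02, 0.9), lfc = c(2, -1, 0.2))
  out <- call_changes(tab, "dhs", q_threshold = 0.05)
  expect_equal(out$q, c(0.003, 0.03, 0.9))
  expect_identical(out$label, c("gain", "loss", "none"))
  # all p = 1: nothing called
  out1 <- call_changes(data.frame(p = rep(1, 5), lfc = rnorm(5)), "dhs")
  expect_true(all(out1$label == "none"))
  # q monotone in p and bounded below by p
  withr::with_seed(6, {
    tab2 <- data.frame(p = runif(200), lfc = rnorm(200))
    out2 <- call_changes(tab2, "dhs")
    o <- order(out2$p)
    expect_true(all(diff(out2$q[o]) >= -1e-12))
    expect_true(all(out2$q >= out2$p - 1e-12))
  })
  # chip mode thresholds raw p
  out3 <- call_changes(data.frame(p = c(5e-4, 0.01), lfc = c(1, 1)), "chip")
  expect_identical(out3$label, c("gain", "none"))
})

test_that("planted gains and losses are recovered at high sensitivity", {
  g <- make_genome(sim_params(seed = 13))
  sg <- simulate_signal_regions(g)
  for (mk in c("DHS", "H3K4me1")) {
    tab <- sg[[mk]]
    wt <- grep("^wt_", names(tab)); tko <- grep("^tko_", names(tab))
    f <- size_factors(tab[, c(wt, tko)])
    res <- test_regions(tab[, wt], tab[, tko], f[seq_along(wt)],
                        f[length(wt) + seq_along(tko)])
    tab$lfc <- res$lfc; tab$p <- res$p
    called <- call_changes(tab, if (mk == "DHS") "dhs" else "chip")
    expect_gte(mean(called$label[tab$truth == "gain"] == "gain"), 0.9)
    expect_gte(mean(called$label[tab$truth == "loss"] == "loss"), 0.9)
    expect_lte(mean(called$label[tab$truth == "none"] != "none"), 0.01)
  }
})

# helper reproducing the pipeline's WT signal track construction
wt_track <- function(tab) {
  wt <- grep("^wt_", names(tab))
  f <- size_factors(tab[, grep("^(wt|tko)_", names(tab))])
  data.frame(chrom = tab$chrom, start = tab$start, end = tab$end,
             signal = rowMeans(sweep(as.matrix(tab[, wt]), 2,
                                     f[seq_along(wt)], "/")),
             called = tab$wt_called, stringsAsFactors = FALSE)
}

test_that("de novo site definitions match planted truth", {
  g <- make_genome(sim_params(seed = 17))
  sg <- simulate_signal_regions(g)
  dhs <- sg$DHS; k1 <- sg$H3K4me1
  cols <- c("region_id", "chrom", "start", "end")
  dn <- call_denovo_dhs(dhs[dhs$tko_called, cols], dhs[dhs$wt_called, cols],
                        wt_track(k1), wt_track(sg$H3K4me3))
  # region called in both conditions is excluded
  expect_false(any(dn$region_id %in%
                     dhs$region_id[dhs$wt_called & dhs$tko_called]))
  truth <- dhs$region_id[dhs$denovo]
  jac <- length(intersect(dn$region_id, truth)) /
    length(union(dn$region_id, truth))
  expect_gte(jac, 0.9)
  dn1 <- call_denovo_k4me1(k1[k1$tko_called, cols], k1[k1$wt_called, cols],
                           wt_track(sg$H3K4me3), wt_track(dhs))
  truth1 <- k1$region_id[k1$denovo]
  jac1 <- length(intersect(dn1$region_id, truth1)) /
    length(union(dn1$region_id, truth1))
  expect_gte(jac1, 0.9)
  # anti-symmetry: swapping conditions gives "lost" sites disjoint from
  # the de novo set
  lost <- call_denovo_dhs(dhs[dhs$wt_called, cols], dhs[dhs$tko_called, cols],
                          wt_track(k1), wt_track(sg$H3K4me3))
  expect_length(intersect(dn$region_id, lost$region_id), 0)
})

test_that("hypergeometric overlap test equals brute-force enumeration", {
  mk_regions <- function(idx)
    data.frame(chrom = "chr1", start = idx * 1000, end = idx * 1000 + 100)
  u <- mk_regions(1:50)
  a <- mk_regions(1:10); b <- mk_regions(6:15)
  r <- overlap_test(a, b, u)
  expect_equal(r$n_overlap, 5)
  expect_equal(r$p, oracle_hyper_p(5, 10, 10, 50), tolerance = 1e-12)
  expect_equal(r$fold, 5 / (10 * 10 / 50))
  # A = B = universe: fold 1, p 1
  r2 <- overlap_test(u, u, u)
  expect_equal(r2$fold, 1)
  expect_equal(r2$p, 1)
  # disjoint sets: fold 0, p ~ 1
  r3 <- overlap_test(mk_regions(1:5), mk_regions(20:24), u)
  expect_equal(r3$fold, 0)
  expect_gt(r3$p, 0.5)
  expect_error(overlap_test(mk_regions(100), b, u), "universe")
})

test_that("concordance cross-tabulates joint calls and planted coupling", {
  ta <- data.frame(region_id = sprintf("r%d", 1:6),
                   label = c("gain", "gain", "loss", "none", "gain", "loss"),
                   lfc = c(2, 1.5, -2, 0, 1, -1))
  tb <- data.frame(region_id = sprintf("r%d", 1:6),
                   label = c("gain", "loss", "loss", "gain", "none", "gain"),
                   lfc = c(1.8, -1, -1.5, 2, 0, 2))
  co <- concordance(ta, tb)
  expect_equal(co$n, 4)
  expect_equal(unname(co$table["gain", "gain"]), 1)
  expect_equal(unname(co$table["gain", "loss"]), 1)
  expect_equal(unname(co$table["loss", "loss"]), 1)
  expect_equal(unname(co$table["loss", "gain"]), 1)
  # perfectly anti-correlated deltas
  tc <- data.frame(region_id = c("x", "y", "z"), label = "gain",
                   lfc = c(1, 2, 3))
  td <- data.frame(region_id = c("x", "y", "z"), label = "loss",
                   lfc = c(-1, -2, -3))
  expect_equal(concordance(tc, td)$spearman, -1)
  # empty sentinel
  e <- concordance(ta[ta$label == "none", ], tb[tb$label == "none", ])
  expect_equal(e$n, 0)
  expect_true(is.na(e$spearman))
})
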