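# Synthetic-data generator: determinism, conservation, planted structure.

test_that("parameter validation names the offending field", {
  expect_error(sim_params(dmr_fraction = 1.5), "dmr_fraction")
  expect_error(sim_params(n_tads = 3), "n_tads")
  expect_error(sim_params(decay_exponent = -1), "decay_exponent")
  expect_error(sim_params(chrom_length = 1234567), "chrom_length")
  expect_error(sim_params(reads_per_matrix = 1e4), "reads_per_matrix")
})

test_that("identical params and seed give identical output", {
  p <- small_params(seed = 42)
  g1 <- make_genome(p); g2 <- make_genome(p)
  expect_identical(g1, g2)
  expect_identical(simulate_methylation(g1), simulate_methylation(g2))
  expect_identical(simulate_signal_regions(g1), simulate_signal_regions(g2))
  expect_identical(simulate_hic(g1, condition = "TKO"),
                   simulate_hic(g2, condition = "TKO"))
  expect_identical(simulate_de_genes(g1), simulate_de_genes(g2))
})

test_that("genome model satisfies its structural invariants", {
  g <- small_genome()
  tads <- g$tads
  for (cn in g$chroms$chrom) {
    tt <- tads[tads$chrom == cn, ]
    expect_true(all(diff(tt$start) > 0))
    expect_true(all(tt$end[-nrow(tt)] <= tt$start[-1]))  # non-overlapping
  }
  expect_true(all(g$genes$start >= 0))
  expect_true(all(g$genes$end <=
                    g$chroms$length[match(g$genes$chrom, g$chroms$chrom)]))
  expect_true(all(g$genes$tss >= g$genes$start & g$genes$tss < g$genes$end))
  # states tile each chromosome without overlap
  for (cn in g$chroms$chrom) {
    st <- g$states[g$states$chrom == cn, ]
    expect_equal(st$start[1], 0)
    expect_equal(st$end[nrow(st)],
                 g$chroms$length[g$chroms$chrom == cn])
    expect_true(all(st$start[-1] == st$end[-nrow(st)]))
  }
})

test_that("gene-density gradient is recovered from the generated genome", {
  # uniform case: each quintile holds ~20% of genes
  g1 <- make_genome(sim_params(seed = 2, gene_density_gradient = 1,
                               n_genes = 20000))
  shares <- tapply(g1$tads$gene_count, g1$tads$gene_quintile, sum) /
    sum(g1$tads$gene_count)
  expect_true(all(abs(shares - 0.2) < 0.02))
  # planted gradient 12 recovered within 20%
  g2 <- make_genome(sim_params(seed = 3, gene_density_gradient = 12,
                               n_tads = 500, n_genes = 10000,
                               chrom_length = 60e6))
  top <- sum(g2$tads$gene_count[g2$tads$gene_quintile == 5])
  bottom <- sum(g2$tads$gene_count[g2$tads$gene_quintile == 1])
  expect_gt(top / bottom, 12 * 0.8)
  expect_lt(top / bottom, 12 * 1.2)
})

test_that("planted methylation truth follows the requested mix and skew", {
  g <- small_genome()
  # dmr_fraction = 0: all null
  m0 <- simulate_methylation(g, small_params(dmr_fraction = 0))
  expect_true(all(m0$truth == "null"))
  # hypo share ~ ratio/(1+ratio) within binomial error
  p <- sim_params(seed = 9, hypo_to_hyper_ratio = 14, dmr_fraction = 0.015,
                  n_meth_sites = 100000L)
  m <- simulate_methylation(make_genome(p))
  n_dmr <- sum(m$truth != "null")
  share <- sum(m$truth == "hypo") / n_dmr
  se <- sqrt((14 / 15) * (1 / 15) / n_dmr)
  expect_lt(abs(share - 14 / 15), 3 * se)
  # skew = 1: planted DMR rate uniform across quintiles
  p1 <- sim_params(seed = 10, dmr_gene_density_skew = 1)
  m1 <- simulate_methylation(make_genome(p1))
  dmr <- m1[m1$truth != "null" & !is.na(m1$gene_quintile), ]
  all_q <- table(m1$gene_quintile[!is.na(m1$gene_quintile)])
  cs <- suppressWarnings(stats::chisq.test(table(factor(dmr$gene_quintile,
                                                        levels = 1:5)),
                                           p = all_q / sum(all_q)))
  expect_gt(cs$p.value, 0.01)
})

test_that("methylation counts stay within the declared chromosomes", {
  g <- small_genome()
  m <- simulate_methylation(g)
  expect_true(all(m$start >= 0))
  expect_true(all(m$end <= g$chroms$length[match(m$chrom, g$chroms$chrom)]))
  expect_true(all(m[c("hpa_wt", "msp_wt", "hpa_tko", "msp_tko")] >= 0))
})

test_that("planted signal-region structure matches its parameters", {
  g <- small_genome()
  # zero fractions: all null
  s0 <- simulate_signal_regions(g, small_params(gain_fraction = 0,
                                                loss_fraction = 0))
  for (mk in names(s0)) expect_true(all(s0[[mk]]$truth == "none"))
  # forced coupling: every DHS gain has an H3K4me1 gain
  s1 <- simulate_signal_regions(g, small_params(concordance_prob = 1))
  dhs_gain <- s1$DHS$region_id[s1$DHS$truth == "gain"]
  k1_gain <- s1$H3K4me1$region_id[s1$H3K4me1$truth == "gain"]
  expect_true(all(dhs_gain %in% k1_gain))
  # coupling proportion ~ concordance_prob within 3 SE
  pbig <- sim_params(seed = 21, n_signal_regions = 40000L,
                     gain_fraction = 0.05, concordance_prob = 0.3)
  sbig <- simulate_signal_regions(make_genome(pbig))
  gains <- sbig$DHS$region_id[sbig$DHS$truth == "gain"]
  k1g <- sbig$H3K4me1$region_id[sbig$H3K4me1$truth == "gain"]
  prop <- mean(gains %in% k1g)
  se <- sqrt(0.3 * 0.7 / length(gains))
  expect_lt(abs(prop - 0.3), 3 * se)
  # repressive marks essentially unchanged
  expect_lt(sum(sbig$H3K9me3$truth != "none"),
            0.05 * sum(sbig$DHS$truth != "none"))
  # region universe is non-overlapping
  r <- sbig$DHS
  o <- order(r$chrom, r$start)
  same <- r$chrom[o][-1] == r$chrom[o][-nrow(r)]
  expect_true(all(r$start[o][-1][same] >= r$end[o][-nrow(r)][same]))
})

test_that("simulated Hi-C matrices are symmetric counts with planted decay", {
  p0 <- small_params(compartment_strength = 0, tad_block_strength = 0,
                     domain_score_shift = 0)
  g0 <- make_genome(p0)
  h <- simulate_hic(g0, condition = "WT")[[1]]
  expect_true(all(h$mat == floor(h$mat)))
  expect_identical(h$mat, t(h$mat))
  expect_true(all(h$mat >= 0))
  # pure power law: fitted exponent within 10% of the planted value
  expect_lt(abs(fit_decay_exponent(h) - p0$decay_exponent), 0.1)
  # homogeneous case: far-apart diagonal bands have lower means
  e <- expected_by_distance(h)$expected
  expect_gt(e$mean[e$distance == 2], e$mean[e$distance == 40])
})

test_that("DE genes are a proportional draw with a down-regulated majority", {
  g <- make_genome(sim_params(seed = 31, n_genes = 10000L))
  de0 <- simulate_de_genes(g, sim_params(seed = 31, de_fraction = 0))
  expect_equal(nrow(de0), 0)
  de <- simulate_de_genes(g)
  expect_equal(nrow(de), round(0.03 * 10000))
  expect_gte(mean(de$direction == "down"), 0.7)
  # quintile shares follow the all-gene shares
  q_de <- g$tads$gene_quintile[match(de$tad_id, g$tads$tad_id)]
  q_all <- g$tads$gene_quintile[match(g$genes$tad_id, g$tads$tad_id)]
  tab_all <- table(factor(q_all, levels = 1:5))
  cs <- suppressWarnings(stats::chisq.test(table(factor(q_de, levels = 1:5)),
                                           p = tab_all / sum(tab_all)))
  expect_gt(cs$p.value, 0.01)
})
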