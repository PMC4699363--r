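# Shared fixtures: a small genome model and simulated data, built once per
# test run. Scales are reduced relative to the package defaults where a
# test only needs structure, not statistical power.

small_params <- function(seed = 11, ...) {
  sim_params(seed = seed, n_chrom = 1L, chrom_length = 8e6, n_tads = 20L,
             n_genes = 300L, n_meth_sites = 3000L,
             n_signal_regions = 600L, reads_per_matrix = 2e5, ...)
}

small_genome <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- make_genome(small_params())
    g
  }
})

# independent two-sided exact binomial p by direct tail summation
oracle_binom_p <- function(x, n, p0) {
  probs <- stats::dbinom(0:n, n, p0)
  lower <- sum(probs[0:x + 1])
  upper <- sum(probs[x:n + 1])
  min(1, 2 * min(lower, upper))
}

# brute-force hypergeometric upper tail by enumeration
oracle_hyper_p <- function(k, n_a, n_b, n_u) {
  sum(vapply(k:min(n_a, n_b), function(i)
    choose(n_b, i) * choose(n_u - n_b, n_a - i) / choose(n_u, n_a),
    numeric(1)))
}

# brute-force per-TAD domain score from a double loop over all cells
oracle_domain_score <- function(mat, bins_in_tad, pseudocount = 1) {
  nb <- nrow(mat)
  intra <- 0; inter <- 0
  for (i in seq_len(nb)) for (j in i:nb) {
    if (i %in% bins_in_tad && j %in% bins_in_tad) intra <- intra + mat[i, j]
    else if (xor(i %in% bins_in_tad, j %in% bins_in_tad))
      inter <- inter + mat[i, j]
  }
  (intra + pseudocount) / (inter + pseudocount)
}

random_contact_matrix <- function(n = 30, seed = 1, chrom = "chrX",
                                  bin_size = 1e5) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n * n, 20), n, n)
    m <- m + t(m)
    contact_matrix(m, chrom = chrom, bin_size = bin_size)
  })
}
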