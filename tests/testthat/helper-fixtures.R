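# Fixtures are built in code; nothing is read from disk.

# random genotype dataset with pop01-style names (Genepop has no
# population-name field, so round-trip identity needs canonical names)
random_dataset <- function(n_pops, n_ind, n_loci, miss_rate = 0.1,
                           seed = 1) {
  set.seed(seed)
  n <- n_pops * n_ind
  al <- matrix(sample(80:120, n * 2 * n_loci, replace = TRUE), nrow = n)
  if (miss_rate > 0) {
    for (l in seq_len(n_loci)) {
      m <- runif(n) < miss_rate
      al[m, c(2 * l - 1, 2 * l)] <- NA
    }
  }
  pops <- sprintf("pop%02d", rep(seq_len(n_pops), each = n_ind))
  ids <- sprintf("ind%03d", seq_len(n))
  genotype_dataset(al, pop = factor(pops, levels = unique(pops)), id = ids)
}

# two-population single-locus toy with fixed genotype counts; used for
# frozen-oracle comparisons (counts: list of c(AA, Aa, aa) per pop)
toy_two_pop <- function(counts1 = c(4, 4, 2), counts2 = c(1, 3, 6)) {
  gm <- function(cnt) {
    rbind(matrix(rep(c(100L, 100L), cnt[1]), ncol = 2, byrow = TRUE),
          matrix(rep(c(100L, 120L), cnt[2]), ncol = 2, byrow = TRUE),
          matrix(rep(c(120L, 120L), cnt[3]), ncol = 2, byrow = TRUE))
  }
  al <- rbind(gm(counts1), gm(counts2))
  genotype_dataset(al, pop = rep(c("p1", "p2"),
                                 c(sum(counts1), sum(counts2))))
}

# small shared ABC reference table, built once per test run
shared_abc <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      scen <- build_scenarios()
      cache <<- list(
        scenarios = scen, priors = prior_spec(),
        ref = suppressWarnings(
          build_reference_table(scen, prior_spec(),
                                n_per_scenario = 1000L, seed = 3L,
                                n_ind = 10L, n_loci = 10L)))
    }
    cache
  }
})

# independent direct-formula Moran's I (double loop; no matrix algebra)
moran_oracle <- function(x, w) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + w[i, j] * (x[i] - xb) * (x[j] - xb)
  (n / sum(w)) * num / sum((x - xb)^2)
}
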