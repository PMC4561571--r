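test_that("allele frequencies are correct and order-invariant", {
  ds <- genotype_dataset(rbind(c(100L, 100L), c(100L, 120L)),
                         pop = c("p1", "p1"))
  af <- allele_frequencies(ds)
  expect_equal(unname(af$freq[[1]]["p1", ]), c(0.75, 0.25))
  big <- random_dataset(3, 12, 4, miss_rate = 0.2, seed = 21)
  perm <- sample(nrow(big$alleles))
  shuf <- genotype_dataset(big$alleles[perm, ], pop = big$ind$pop[perm],
                           id = big$ind$id[perm], loci = big$loci)
  a1 <- allele_frequencies(big)
  a2 <- allele_frequencies(shuf)
  expect_equal(a1$freq, a2$freq)
  # all-missing cell flagged
  al <- rbind(c(100L, 100L), c(NA_integer_, NA_integer_))
  ds2 <- genotype_dataset(al, pop = c("p1", "p2"))
  expect_true(allele_frequencies(ds2)$empty[2, 1])
})

test_that("diversity matches closed forms on simple cells", {
  ds <- genotype_dataset(rbind(c(100L, 120L), c(100L, 120L)),
                         pop = c("p1", "p1"))
  dv <- diversity(ds, g = 2)
  expect_equal(dv$He, 0.5)
  expect_equal(dv$Ho, 1)
  mono <- genotype_dataset(rbind(c(100L, 100L), c(100L, 100L)),
                           pop = c("p1", "p1"))
  dm <- diversity(mono, g = 2)
  expect_equal(dm$He, 0)
  expect_equal(dm$richness, 1)
})

test_that("rarefied richness at g = 2 equals one plus unbiased He", {
  # hypergeometric expectation at two genes reduces to
  # 1 + (2n / (2n - 1)) (1 - sum p^2); cross-checked by direct
  # enumeration over all pairs of gene copies
  set.seed(31)
  al <- matrix(sample(c(100L, 104L, 108L), 60, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2)), ncol = 2)
  ds <- genotype_dataset(al, pop = rep("p1", 30))
  dv <- diversity(ds, g = 2, unbiased = TRUE)
  expect_equal(dv$richness, 1 + dv$He, tolerance = 1e-12)
  # enumeration oracle: expected distinct alleles in a random pair
  copies <- as.vector(al)
  n2 <- length(copies)
  pairs_distinct <- 0
  for (i in 1:(n2 - 1)) for (j in (i + 1):n2)
    pairs_distinct <- pairs_distinct + (copies[i] != copies[j])
  expect_equal(dv$richness, 1 + pairs_distinct / choose(n2, 2),
               tolerance = 1e-12)
})

test_that("HWE exact p matches full enumeration on the two-homozygote
           fixture", {
  ds <- genotype_dataset(rbind(c(100L, 100L), c(120L, 120L)),
                         pop = c("p1", "p1"))
  # Levene: config {AA, aa} has probability 1/3, {Aa, Aa} has 2/3
  expect_equal(hwe_exact(ds, 1, 1, method = "enumerate"), 1 / 3,
               tolerance = 1e-12)
  mono <- genotype_dataset(rbind(c(100L, 100L)), pop = "p1")
  expect_equal(hwe_exact(mono, 1, 1), 1)
})

test_that("Monte-Carlo HWE p converges to the enumerated p", {
  set.seed(41)
  al <- matrix(sample(c(100L, 104L, 108L), 80, replace = TRUE), ncol = 2)
  ds <- genotype_dataset(al, pop = rep("p1", 40))
  p_enum <- hwe_exact(ds, 1, 1, method = "enumerate")
  p_mc <- hwe_exact(ds, 1, 1, method = "mc", mc_reps = 1e6, seed = 5)
  expect_lt(abs(p_enum - p_mc), 0.01)
})

test_that("LD test flags perfectly coupled loci and is 1 for monomorphic
           ones", {
  set.seed(51)
  a <- matrix(sample(c(100L, 110L), 60, replace = TRUE), ncol = 2)
  ds <- genotype_dataset(cbind(a, a), pop = rep("p1", 30),
                         loci = c("A", "B"))
  expect_lte(ld_genotypic(ds, "A", "B", "p1", n_perm = 999, seed = 1),
             0.001)
  mono <- genotype_dataset(cbind(a, matrix(100L, 30, 2)),
                           pop = rep("p1", 30), loci = c("A", "B"))
  expect_equal(ld_genotypic(mono, "A", "B", "p1"), 1)
})

test_that("Fisher combination behaves at the boundaries", {
  expect_equal(fisher_combine(rep(1, 5)), 1)
  expect_lt(fisher_combine(rep(0.01, 5)), 1e-4)
})

test_that("Holm correction reproduces the hand-worked example", {
  hc <- holm_correction(c(0.01, 0.04), alpha = 0.05)
  expect_true(all(hc$reject)) # 0.01 <= 0.05/2 and 0.04 <= 0.05/1
  expect_equal(hc$adjusted, c(0.02, 0.04))
  one <- holm_correction(0.03)
  expect_equal(one$adjusted, 0.03)
  expect_false(any(holm_correction(rep(1, 10))$reject))
})

test_that("theta equals the independent direct-formula oracle on fixed
           toys", {
  # frozen values from an independent implementation of the 1984
  # component equations
  expect_equal(wc_theta(toy_two_pop(c(4, 4, 2), c(1, 3, 6)))$theta,
               0.1717171717171717, tolerance = 1e-10)
  expect_equal(wc_theta(toy_two_pop(c(6, 2, 1), c(2, 5, 8)))$theta,
               0.3302399593796327, tolerance = 1e-10)
})

test_that("theta is 1 for fixed differences and near 0 for a duplicated
           population", {
  fixed <- genotype_dataset(rbind(matrix(100L, 5, 4), matrix(120L, 5, 4)),
                            pop = rep(c("p1", "p2"), each = 5))
  expect_equal(wc_theta(fixed)$theta, 1)
  g <- simulate_island_genotypes(
    island_model_spec(1, 40, 10, N = 500, m = 0, mu = 1e-3), seed = 61)
  dup <- genotype_dataset(g$alleles,
                          pop = rep(c("pA", "pB"), 20), loci = g$loci)
  th <- wc_theta(dup, n_perm = 199, seed = 2)
  expect_lt(abs(th$theta), 0.05)
  expect_gt(th$p, 0.05)
})

test_that("theta, R_ST, AMOVA and Nei D are invariant to population and
           individual order", {
  ds <- simulate_island_genotypes(
    island_model_spec(8, 8, 6, N = 200, m = 0.002, mu = 1e-3), seed = 71)
  meta <- data.frame(population = populations(ds),
                     state = rep(c("IN", "OH", "NC", "TN"), each = 2),
                     lat = 35, lon = -80)
  ds <- attach_metadata(ds, meta)
  perm <- sample(nrow(ds$alleles))
  shuf <- genotype_dataset(ds$alleles[perm, ], pop = ds$ind$pop[perm],
                           id = ds$ind$id[perm], loci = ds$loci,
                           meta = meta)
  expect_equal(wc_theta(shuf)$theta, wc_theta(ds)$theta)
  expect_equal(rst(shuf)$rst, rst(ds)$rst)
  expect_equal(amova(shuf)$F, amova(ds)$F)
  expect_equal(unclass(nei_distance(shuf)), unclass(nei_distance(ds)))
})

test_that("jackknife CI brackets theta and narrows with more loci", {
  se_for <- function(L) {
    mean(sapply(1:10, function(s) {
      ds <- simulate_island_genotypes(
        island_model_spec(4, 10, L, N = 200, m = 0.00125, mu = 2e-4),
        seed = s)
      wc_theta(ds)$se
    }))
  }
  expect_lt(se_for(60), se_for(15))
  ds <- simulate_island_genotypes(
    island_model_spec(4, 10, 15, N = 200, m = 0.00125, mu = 2e-4),
    seed = 3)
  th <- wc_theta(ds)
  expect_true(th$ci[1] <= th$theta && th$theta <= th$ci[2])
})

test_that("pairwise F_ST matrix is symmetric with a zero diagonal and
           detects strong structure", {
  ds <- simulate_island_genotypes(
    island_model_spec(4, 30, 15, N = 200, m = 0.25 / (4 * 200),
                      mu = 5e-4), seed = 81)
  pw <- pairwise_fst_matrix(ds, n_perm = 999, seed = 4)
  expect_equal(pw$fst, t(pw$fst))
  expect_equal(unname(diag(pw$fst)), rep(0, 4))
  expect_true(all(pw$significant[upper.tri(pw$significant)]))
})

test_that("R_ST responds to allele-size relabelling while theta does not", {
  # three unevenly spaced alleles: permuting which size plays which role
  # rearranges the size variance (R_ST) but not allele identity (theta)
  set.seed(3)
  al <- matrix(sample(c(100L, 102L, 120L), 80, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2)), ncol = 2)
  ds <- genotype_dataset(al, pop = rep(c("p1", "p2"), each = 20))
  relab <- ds
  relab$alleles[al == 102L] <- 120L
  relab$alleles[al == 120L] <- 102L
  expect_equal(wc_theta(relab)$theta, wc_theta(ds)$theta)
  expect_false(isTRUE(all.equal(rst(relab)$rst, rst(ds)$rst)))
  fixed <- genotype_dataset(rbind(matrix(100L, 5, 2), matrix(120L, 5, 2)),
                            pop = rep(c("p1", "p2"), each = 5))
  expect_equal(rst(fixed)$rst, 1)
  mono <- genotype_dataset(matrix(100L, 6, 2), pop = rep(c("a", "b"), 3))
  expect_error(rst(mono), "monomorphic")
})

test_that("R_ST equals a two-level variance-components oracle via aov", {
  ds <- toy_two_pop(c(3, 5, 2), c(6, 2, 2))
  # oracle: classic ANOVA on allele sizes with aov, components by
  # method of moments
  m <- ds$alleles
  y <- c(m[, 1], m[, 2])
  g <- factor(rep(as.character(ds$ind$pop), 2))
  av <- summary(stats::aov(y ~ g))[[1]]
  msa <- av["g", "Mean Sq"]; msw <- av["Residuals", "Mean Sq"]
  ni <- as.vector(table(g)); ntot <- sum(ni)
  n0 <- (ntot - sum(ni^2) / ntot) / (length(ni) - 1)
  s2a <- (msa - msw) / n0
  expect_equal(rst(ds)$rst, s2a / (s2a + msw), tolerance = 1e-10)
})

test_that("AMOVA components match the balanced nested-ANOVA oracle", {
  # balanced toy: 2 regions x 2 states x 2 pops x 4 individuals, one locus
  set.seed(91)
  n_ind <- 32
  al <- matrix(sample(c(100L, 120L), 64, replace = TRUE), ncol = 2)
  pops <- rep(sprintf("p%d", 1:8), each = 4)
  ds <- genotype_dataset(al, pop = pops)
  meta <- data.frame(population = sprintf("p%d", 1:8),
                     state = rep(c("IN", "OH", "NC", "TN"), each = 2),
                     lat = 35, lon = -80)
  ds <- attach_metadata(ds, meta)
  am <- amova(ds)
  # oracle: textbook balanced EMS solved from mean squares computed by
  # explicit group means on the allele indicator, allele-identity scale
  y <- as.numeric(c(al[, 1], al[, 2]) == 100L)
  ind <- rep(1:32, 2)
  popv <- rep(rep(1:8, each = 4), 2)
  st <- (popv + 1) %/% 2
  rg <- (st + 1) %/% 2
  ssw <- function(g) {
    tot <- 0
    for (k in unique(g)) {
      yy <- y[g == k]
      tot <- tot + sum((yy - mean(yy))^2)
    }
    tot
  }
  SS_tot <- sum((y - mean(y))^2)
  SS <- c(region = SS_tot - ssw(rg), state = ssw(rg) - ssw(st),
          pop = ssw(st) - ssw(popv), ind = ssw(popv) - ssw(ind),
          within = ssw(ind))
  MS <- SS / c(1, 2, 4, 24, 32)
  sg <- MS[["within"]]
  si <- (MS[["ind"]] - sg) / 2
  sp <- (MS[["pop"]] - sg - 2 * si) / 8
  ss_ <- (MS[["state"]] - sg - 2 * si - 8 * sp) / 16
  sr <- (MS[["region"]] - sg - 2 * si - 8 * sp - 16 * ss_) / 32
  oracle <- c(sr, ss_, sp, si, sg)
  expect_equal(unname(am$sigma), unname(oracle), tolerance = 1e-8)
})

test_that("AMOVA F statistics behave at the extremes and under random
           labels", {
  # regions fixed for different alleles: F_RT -> 1
  al <- rbind(matrix(100L, 16, 2), matrix(120L, 16, 2))
  ds <- genotype_dataset(al, pop = rep(sprintf("p%d", 1:8), each = 4))
  meta <- data.frame(population = sprintf("p%d", 1:8),
                     state = rep(c("IN", "OH", "NC", "TN"), each = 2),
                     lat = 35, lon = -80)
  ds <- attach_metadata(ds, meta)
  am <- amova(ds)
  expect_gt(am$F[["F_RT"]], 0.95)
  expect_equal(am$F[["F_IT"]], 1, tolerance = 1e-8)
  # panmictic data with arbitrary labels: all F near 0
  g <- simulate_island_genotypes(
    island_model_spec(8, 6, 10, N = 500, m = 0.5, mu = 1e-3), seed = 13)
  meta8 <- data.frame(population = populations(g),
                      state = rep(c("IN", "OH", "NC", "TN"), each = 2),
                      lat = 35, lon = -80)
  g <- attach_metadata(g, meta8)
  am0 <- amova(g, n_perm = 49, seed = 1)
  expect_lt(max(abs(am0$F[c("F_RT", "F_SR", "F_PS")])), 0.05)
  expect_gt(am0$p[["F_PS"]], 0.05)
})

test_that("single-level AMOVA collapses to theta on balanced designs", {
  # exact identity on the toy (components coincide allele by allele)
  toy <- attach_metadata(toy_two_pop(c(4, 4, 2), c(1, 3, 6)),
                         data.frame(population = c("p1", "p2"),
                                    state = "TN", lat = 35, lon = -86))
  expect_equal(amova(toy)$F[["F_PS"]], wc_theta(toy)$theta,
               tolerance = 1e-10)
  # near-identity on simulated data (they differ only through the
  # truncation of a small negative among-individual component)
  ds <- simulate_island_genotypes(
    island_model_spec(4, 30, 20, N = 500, m = 5e-4, mu = 1e-3),
    seed = 15)
  meta <- data.frame(population = populations(ds), state = "TN",
                     lat = 35, lon = -86)
  ds <- attach_metadata(ds, meta)
  am <- amova(ds)
  expect_lt(abs(am$F[["F_PS"]] - wc_theta(ds)$theta), 0.01)
})

test_that("null-allele EM is near zero without excess and consistent with
           the unadjusted theta", {
  g <- simulate_island_genotypes(
    island_model_spec(2, 100, 8, N = 500, m = 0.005, mu = 1e-3),
    seed = 17)
  em <- suppressWarnings(null_allele_em(g))
  expect_lt(mean(em$r0), 0.02)
  expect_true(all(em$converged))
  th0 <- wc_theta(g)$theta
  thc <- fst_excluding_null(g, em)$theta
  expect_lt(abs(th0 - thc), 0.005)
})

test_that("Nei distance matches hand arithmetic and its degenerate cases", {
  # one locus, freqs (.5, .5) vs (.9, .1):
  # D = -ln(0.5 / sqrt(0.5 * 0.82))
  ds <- genotype_dataset(
    rbind(matrix(c(100L, 100L, 100L, 120L, 100L, 120L, 120L, 120L,
                   100L, 120L), ncol = 2, byrow = TRUE),
          matrix(c(100L, 100L, 100L, 100L, 100L, 100L, 100L, 100L,
                   100L, 120L), ncol = 2, byrow = TRUE)),
    pop = rep(c("p1", "p2"), each = 5))
  D <- nei_distance(ds)
  expect_equal(D["p1", "p2"], -log(0.5 / sqrt(0.5 * 0.82)),
               tolerance = 1e-12)
  # identical profiles -> 0
  same <- genotype_dataset(rbind(c(100L, 120L), c(100L, 120L)),
                           pop = c("p1", "p2"))
  expect_equal(nei_distance(same)["p1", "p2"], 0)
  expect_equal(cse_chord(same)["p1", "p2"], 0)
  # disjoint alleles -> infinite, flagged
  disj <- genotype_dataset(rbind(c(100L, 100L), c(120L, 120L)),
                           pop = c("p1", "p2"))
  expect_true(is.infinite(nei_distance(disj)["p1", "p2"]))
  expect_true(attr(nei_distance(disj), "infinite"))
})

test_that("PHYLIP square export round-trips through read.table", {
  ds <- toy_two_pop()
  nd <- nei_distance(ds)
  f <- tempfile()
  write_phylip(nd, f)
  lines <- readLines(f)
  expect_equal(as.integer(trimws(lines[1])), 2L)
  vals <- as.numeric(strsplit(trimws(substring(lines[2], 11)),
                              "[[:space:]]+")[[1]])
  expect_equal(vals, unname(nd[1, ]), tolerance = 1e-5)
  unlink(f)
})

test_that("linearized F_ST is the Rousset transform", {
  m <- matrix(c(0, 0.2, 0.2, 0), 2)
  expect_equal(linearized_fst(m)[1, 2], 0.25)
  expect_equal(diag(linearized_fst(m)), c(0, 0))
})
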