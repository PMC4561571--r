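test_that("scenario construction honours the design and ordering
           constraints", {
  scen <- build_scenarios()
  expect_equal(length(scen), 3L)
  expect_equal(scen[[1]]$admixture, "none")
  expect_error(build_scenarios(regions = c("NC", "NC", "NC", "TN")),
               "2\\+2")
  pri <- prior_spec()
  set.seed(23)
  for (i in 1:200) {
    p2 <- draw_params(scen[[2]], pri)
    expect_gt(p2$t4, p2$t3)
    expect_true(p2$tw2 < p2$t4 && p2$t4 < p2$tw1)
    p3 <- draw_params(scen[[3]], pri)
    expect_lt(p3$t5, p3$t3)
    expect_gte(p3$t5, 2)
    expect_true(p2$t2 <= p2$t1 && p2$tw1 < p2$t2)
    expect_true(p2$r > 0.1 - 1e-9 && p2$r < 0.9 + 1e-9)
    expect_equal(p2$N_1, 0.1 * p2$N_e)
  }
  # scenario 1 events contain no admixture
  ev <- resmosaic:::scenario_events(scen[[1]],
                                    draw_params(scen[[1]], pri))
  expect_false(any(ev[, 2] == 2))
})

test_that("the scenario coalescent hits analytic anchors", {
  scen <- build_scenarios()
  pri <- prior_spec()
  # mu = 0: every individual shares one allele per locus
  pars <- draw_params(scen[[1]], pri)
  pars$mu <- 0
  ds <- simulate_coalescent_ssr(scen[[1]], pars, n_ind = 5, n_loci = 4,
                                seed = 29)
  for (l in 1:4)
    expect_equal(length(unique(as.vector(
      resmosaic:::locus_alleles(ds, l)))), 1L)
  # deterministic under seed
  pars2 <- draw_params(scen[[2]], pri)
  expect_identical(
    simulate_coalescent_ssr(scen[[2]], pars2, seed = 31)$alleles,
    simulate_coalescent_ssr(scen[[2]], pars2, seed = 31)$alleles)
})

test_that("two-lineage TMRCA matches the coalescent expectation within
           2%", {
  sp <- island_model_spec(1, 1, 5000, N = 800, m = 0, mu = 1e-9)
  g <- simulate_island_genotypes(sp, seed = 37)
  expect_lt(abs(mean(attr(g, "tmrca")) - 2 * 800) / (2 * 800), 0.02)
})

test_that("deep divergence without migration yields strong pairwise
           differentiation", {
  scen <- build_scenarios()
  # explicit geometry: recent within-region splits (just above the
  # bottleneck), deep regional divergence, weak mutation
  pars <- list(N_e = 250, N_1 = 25, t1 = 210, t2 = 205, t3 = 39,
               t4 = 100, t5 = 10, tw1 = 41, tw2 = 41, r = 0.5, mu = 2e-4)
  ss <- rowMeans(sapply(1:5, function(sd) {
    ds <- simulate_coalescent_ssr(scen[[1]], pars, n_ind = 18,
                                  n_loci = 15, seed = 40 + sd)
    summary_stats(ds)
  }))
  within <- mean(ss[c("theta_NC1.NC2", "theta_TN1.TN2")])
  between <- mean(ss[c("theta_NC1.TN1", "theta_NC1.TN2",
                       "theta_NC2.TN1", "theta_NC2.TN2")])
  expect_gt(between, within)
  # divergence-dominated limit: deep split at small sizes gives theta
  # at least 0.5
  expect_gte(between, 0.5)
})

test_that("summary vector has the contract length and exchangeable loci", {
  scen <- build_scenarios()
  pars <- draw_params(scen[[1]], prior_spec())
  ds <- simulate_coalescent_ssr(scen[[1]], pars, n_ind = 8, n_loci = 6,
                                seed = 43)
  ss <- summary_stats(ds)
  P <- 4
  expect_equal(length(ss), 4 * P + 2 * P * (P - 1) / 2)
  expect_false(anyNA(ss))
  # locus order must not matter
  perm <- sample(6)
  cols <- as.vector(rbind(2 * perm - 1, 2 * perm))
  ds2 <- genotype_dataset(ds$alleles[, cols], pop = ds$ind$pop,
                          id = ds$ind$id, loci = ds$loci[perm])
  expect_equal(summary_stats(ds2), ss, tolerance = 1e-12)
})

test_that("a duplicated population collapses its pairwise summaries", {
  g <- simulate_island_genotypes(
    island_model_spec(1, 36, 10, N = 500, m = 0, mu = 1e-3), seed = 47)
  dup <- genotype_dataset(g$alleles, pop = rep(c("A", "B"), 18),
                          loci = g$loci)
  ss <- summary_stats(dup)
  expect_lt(abs(ss[["theta_A.B"]]), 0.05)
  expect_lt(ss[["dmu2_A.B"]], 1)
})

test_that("reference table is balanced, reproducible and inside the
           priors", {
  sh <- shared_abc()
  ref <- sh$ref
  expect_equal(as.vector(table(ref$scenario)), rep(1000L, 3))
  expect_true(all(ref$N_e >= 250 & ref$N_e <= 1000))
  expect_true(all(ref$mu >= 1e-4 & ref$mu <= 1e-3))
  expect_true(all(ref$t5 >= 2 & ref$t5 <= 38))
  expect_true(all(ref$r >= 0.1 & ref$r <= 0.9))
  # reproducibility of the construction
  ref2 <- suppressWarnings(
    build_reference_table(sh$scenarios, sh$priors,
                          n_per_scenario = 1000L, seed = 3L,
                          n_ind = 10L, n_loci = 10L))
  expect_identical(as.data.frame(ref), as.data.frame(ref2))
  expect_error(build_reference_table(sh$scenarios, sh$priors,
                                     n_per_scenario = 10), "too sparse")
})

test_that("reference table round-trips through its TSV + sidecar", {
  sh <- shared_abc()
  path <- file.path(tempdir(), "ref.tsv")
  write_reference_table(sh$ref, path)
  back <- read_reference_table(path)
  expect_equal(attr(back, "stat_cols"), attr(sh$ref, "stat_cols"))
  expect_equal(as.data.frame(back), as.data.frame(sh$ref),
               tolerance = 1e-6)
  unlink(c(path, paste0(path, ".json")))
})

test_that("model choice returns coherent probabilities and honours the
           nearest-neighbour limit", {
  sh <- shared_abc()
  obs <- unlist(sh$ref[5, attr(sh$ref, "stat_cols")])
  res <- abc_model_choice(sh$ref, obs, tolerance = 0.02)
  expect_equal(sum(res$direct), 1, tolerance = 1e-9)
  expect_equal(sum(res$logistic), 1, tolerance = 1e-9)
  expect_true(all(res$ci["lower", ] <= res$ci["upper", ], na.rm = TRUE))
  expect_error(abc_model_choice(sh$ref, obs, tolerance = 0), "tolerance")
  expect_error(abc_model_choice(sh$ref, obs[-1]), "does not match")
})

test_that("model choice is invariant to affine rescaling of a summary
           column", {
  sh <- shared_abc()
  obs <- unlist(sh$ref[10, attr(sh$ref, "stat_cols")])
  r1 <- abc_model_choice(sh$ref, obs, tolerance = 0.02)
  ref2 <- sh$ref
  cn <- attr(sh$ref, "stat_cols")[1]
  ref2[[cn]] <- 100 * ref2[[cn]] + 7
  obs2 <- obs
  obs2[cn] <- 100 * obs2[cn] + 7
  r2 <- abc_model_choice(ref2, obs2, tolerance = 0.02)
  expect_equal(r1$direct, r2$direct, tolerance = 1e-9)
  expect_equal(r1$logistic, r2$logistic, tolerance = 1e-3)
})

test_that("a well-separated synthetic table makes the true cluster
           dominate", {
  # hand-built reference table with three separated clusters
  set.seed(53)
  n <- 600
  stats_m <- rbind(cbind(rnorm(n, 0), rnorm(n, 0)),
                   cbind(rnorm(n, 8), rnorm(n, 0)),
                   cbind(rnorm(n, 0), rnorm(n, 8)))
  tab <- data.frame(scenario = rep(1:3, each = n),
                    s1 = stats_m[, 1], s2 = stats_m[, 2])
  attr(tab, "stat_cols") <- c("s1", "s2")
  class(tab) <- c("abc_reference", "data.frame")
  res <- abc_model_choice(tab, c(s1 = 8, s2 = 0), tolerance = 0.05)
  expect_gt(res$logistic[["scenario2"]], 0.5)
  expect_equal(which.max(res$direct), 2L, ignore_attr = TRUE)
  # tightening the tolerance must not change the argmax here
  res2 <- abc_model_choice(tab, c(s1 = 8, s2 = 0), tolerance = 0.01)
  expect_equal(which.max(res2$logistic), 2L, ignore_attr = TRUE)
  # direct and logistic agree when separation is clean
  expect_lt(max(abs(res$direct - res$logistic)), 0.15)
})

test_that("confusion matrix rows are proper distributions", {
  sh <- shared_abc()
  cm <- confusion_matrix(sh$ref, sh$scenarios, sh$priors, n_pods = 4L,
                         tolerance = 0.02, seed = 5)
  expect_equal(unname(rowSums(cm)), rep(1, 3))
  expect_true(all(cm >= 0 & cm <= 1))
})
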