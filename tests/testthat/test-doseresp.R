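test_that("replicate adjustment preserves the grand mean and removes the
           between-greenhouse difference", {
  sp <- dose_sim_spec(stats::setNames(rep(1.6, 20), sprintf("p%02d", 1:20)),
                      b = 2, c_upper = 0.9, n_per_dose = 17,
                      replicate_shift = -1) # n = 2040
  ph <- simulate_dose_response(sp, seed = 11)
  adj <- adjust_for_replicate(ph)
  expect_equal(mean(adj$adjusted), mean(ph$survival))
  raw_gap <- abs(diff(tapply(ph$survival, ph$replicate, mean)))
  adj_gap <- abs(diff(tapply(adj$adjusted, adj$replicate, mean)))
  expect_lt(adj_gap, 0.1 * raw_gap)
})

test_that("adjustment is a no-op when replicates already agree, and falls
           back on separation", {
  tb <- data.frame(replicate = rep(1:2, each = 50),
                   survival = rep(c(0L, 1L), 50))
  adj <- adjust_for_replicate(tb)
  expect_equal(adj$adjusted, as.numeric(tb$survival), tolerance = 1e-10)
  sep <- data.frame(replicate = rep(1:2, each = 4),
                    survival = c(rep(1L, 4), 0L, 1L, 0L, 1L))
  expect_warning(out <- adjust_for_replicate(sep), "separation")
  expect_equal(out$adjusted, as.numeric(sep$survival))
  expect_error(adjust_for_replicate(data.frame(replicate = 1,
                                               survival = 1)),
               ">= 2 replicate")
})

test_that("noiseless curve data recover the parameters to 4 significant
           digits", {
  doses <- c(0, 0.21, 0.42, 0.84, 1.70, 3.40)
  y <- resmosaic:::weibull_curve(doses, 1, 0, 2, 1.6)
  f <- fit_weibull(doses, y, mode = "ls")
  expect_true(f$converged)
  expect_equal(f$c, 1, tolerance = 1e-4)
  expect_equal(f$d, 0, tolerance = 1e-4)
  expect_equal(f$b, 2, tolerance = 1e-4)
  expect_equal(f$e, 1.6, tolerance = 1e-4)
})

test_that("the curve passes through its analytic anchor points", {
  f <- list(c = 0.8, d = 0.1, b = 3, e = 1.2)
  expect_equal(resmosaic:::weibull_curve(1.2, f$c, f$d, f$b, f$e),
               f$d + (f$c - f$d) * exp(-1))
  expect_equal(resmosaic:::weibull_curve(0, f$c, f$d, f$b, f$e), f$c)
  # monotone non-increasing, limits reached
  xs <- seq(0, 100, length.out = 2000)
  ys <- resmosaic:::weibull_curve(xs, f$c, f$d, f$b, f$e)
  expect_true(all(diff(ys) <= 1e-12))
  expect_lt(abs(resmosaic:::weibull_curve(1e6 * f$e, f$c, f$d, f$b, f$e) -
                  f$d), 1e-9)
})

test_that("fit refuses designs with too few positive doses", {
  expect_error(fit_weibull(c(0, 1, 2, 1, 2), c(1, 0.5, 0.2, 0.5, 0.2)),
               ">= 4 distinct")
})

test_that("closed-form ED50 agrees with numeric inversion of the curve", {
  f <- fit_weibull(c(0, 0.21, 0.42, 0.84, 1.7, 3.4),
                   resmosaic:::weibull_curve(c(0, 0.21, 0.42, 0.84, 1.7,
                                               3.4), 1, 0, 2, 1.6),
                   mode = "ls")
  est <- ed50(f)
  expect_equal(est$ed50, f$e * log(2)^(1 / f$b), tolerance = 1e-12)
  # numeric-root oracle: solve Y(x) = (c+d)/2 directly
  root <- uniroot(function(x)
    resmosaic:::weibull_curve(x, f$c, f$d, f$b, f$e) - (f$c + f$d) / 2,
    c(1e-6, 100), tol = 1e-12)$root
  expect_equal(est$ed50, root, tolerance = 1e-8)
})

test_that("ED50 closed form matches hand arithmetic", {
  mk <- function(b, e) structure(list(c = 1, d = 0, b = b, e = e,
                                      vcov_loge_b = matrix(NA, 2, 2)),
                                 class = "weibull_fit")
  expect_equal(ed50(mk(1, 1))$ed50, log(2), tolerance = 1e-12)
  expect_equal(ed50(mk(2, 1.6))$ed50, 1.6 * sqrt(log(2)),
               tolerance = 1e-12)
  expect_equal(ed50(mk(1e6, 2.5))$ed50, 2.5, tolerance = 1e-4)
  expect_error(ed50(mk(-1, 1)), "positive")
})

test_that("bootstrap species CI is degenerate-safe, bounded and matches
           the binomial enumeration oracle", {
  flat <- bootstrap_species_ci(rep(0.6, 10), B = 500, seed = 1)
  expect_equal(c(flat$lower, flat$upper), c(0.6, 0.6))
  pm <- c(runif(8), 0, 1)
  ci <- bootstrap_species_ci(pm, B = 2000, seed = 2)
  expect_gte(ci$lower, min(pm))
  expect_lte(ci$upper, max(pm))
  expect_true(ci$lower <= ci$mean && ci$mean <= ci$upper)
  # resampling 10 zeros and 10 ones: the mean is X/20 with X ~ Bin(20, .5),
  # whose 2.5% and 97.5% quantiles are 6 and 14
  ci2 <- bootstrap_species_ci(c(rep(0, 10), rep(1, 10)), B = 10000,
                              seed = 3)
  expect_equal(ci2$lower, qbinom(0.025, 20, 0.5) / 20, tolerance = 0.02)
  expect_equal(ci2$upper, qbinom(0.975, 20, 0.5) / 20, tolerance = 0.02)
})

test_that("classification uses a closed interval", {
  ci <- list(lower = 0.3, upper = 0.7)
  out <- classify_populations(c(a = 0.7, b = 0.9, c = 0.1, d = 0.5), ci)
  expect_equal(out$label, c("within", "above", "below", "within"))
})

test_that("planted resistant populations are classified above the species
           CI", {
  hits <- sapply(1:10, function(s) {
    truth <- c(rep(0.9, 12), rep(0.45, 32))
    set.seed(s)
    means <- rbinom(44, 20, truth) / 20
    ci <- bootstrap_species_ci(means, B = 1000, seed = s)
    sum(classify_populations(means, ci)$label[1:12] == "above")
  })
  expect_gte(mean(hits == 12), 0.95)
})

test_that("ed50_table fits per scope and flags convergence", {
  sp <- dose_sim_spec(stats::setNames(rep(1.6, 8), sprintf("p%02d", 1:8)),
                      b = 2, c_upper = 0.95, n_per_dose = 30)
  ph <- simulate_dose_response(sp, seed = 12)
  meta <- data.frame(population = sprintf("p%02d", 1:8),
                     state = rep(c("TN", "OH"), each = 4),
                     lat = 36, lon = -86)
  ph <- attach_metadata(ph, meta)
  tab <- rbind(ed50_table(ph, by = "species"),
               ed50_table(ph, by = "region"))
  expect_equal(tab$group, c("species", "MW", "SE"))
  expect_true(all(tab$converged))
  expect_true(all(abs(tab$ed50 - 1.6) / 1.6 < 0.25))
})
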