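## Approximate Bayesian computation: coalescent simulation of SSR data
## under three demographic scenarios (no admixture, admixture before the
## onset of widespread herbicide use, admixture after), and model choice
## by rejection sampling refined with a local multinomial logistic
## regression.

#' Prior specification for the demographic scenarios
#'
#' Defaults: ancestral effective size `N_e ~ U(250, 1000)` with a
#' bottleneck to `N_1 = 0.1 N_e` at `t3 = 39` generations before present
#' (1974 for a 2013 sample of an annual plant); species origin
#' `t1 ~ U(180, 210)`; regional divergence `t2 ~ U(t3 + 1, t1)`;
#' within-region splits `t_w ~ U(t3 + 1, t2)`; pre-herbicide admixture
#' time `t4 ~ U(t3 + 1, t2)`; post-herbicide admixture time
#' `t5 ~ U{2, ..., 38}` (integer); admixture proportion `r ~ U(0.1, 0.9)`;
#' SSR stepwise mutation rate `mu ~ LogUniform(1e-4, 1e-3)` per locus per
#' generation.
#'
#' @param ne_range,t1_range,t5_range,r_range,mu_range prior ranges.
#' @param t3 fixed bottleneck time (generations).
#' @param bottleneck_factor recent size as a fraction of `N_e`.
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(ne_range = c(250, 1000), t1_range = c(180, 210),
                       t5_range = c(2L, 38L), r_range = c(0.1, 0.9),
                       mu_range = c(1e-4, 1e-3), t3 = 39,
                       bottleneck_factor = 0.1) {
  structure(list(ne_range = ne_range, t1_range = t1_range,
                 t5_range = t5_range, r_range = r_range,
                 mu_range = mu_range, t3 = t3,
                 bottleneck_factor = bottleneck_factor),
            class = "prior_spec")
}

#' Build the three admixture scenarios
#'
#' All scenarios share the topology (four sampled populations, two per
#' region, within-region splits, a regional divergence at `t2`, a
#' 90%-bottleneck at `t3`) and differ only in the admixture event:
#' scenario 1 has none, scenario 2 admixes at `t4 > t3` (before herbicide
#' use), scenario 3 at `t5 < t3` (after).  The recipient is the first
#' population of the first region, the donor the first population of the
#' second region.
#'
#' @param pops four population labels.
#' @param regions region label per population; must split 2 + 2.
#' @return list of three `demographic_scenario` objects.
#' @export
build_scenarios <- function(pops = c("NC1", "NC2", "TN1", "TN2"),
                            regions = c("NC", "NC", "TN", "TN")) {
  if (length(pops) != 4L || length(regions) != 4L)
    stop("the sampling design is four populations")
  tab <- table(regions)
  if (length(tab) != 2L || any(tab != 2L))
    stop("sample design without a 2+2 regional split")
  ord <- order(match(regions, unique(regions)))
  pops <- pops[ord]; regions <- regions[ord]
  lapply(1:3, function(id) {
    structure(list(id = id,
                   name = c("no admixture", "pre-herbicide admixture",
                            "post-herbicide admixture")[id],
                   pops = pops, regions = regions,
                   admixture = c("none", "pre", "post")[id]),
              class = "demographic_scenario")
  })
}

#' Draw one parameter set from the priors, honouring scenario constraints
#'
#' Ordering constraints (`t5 < t3 < t4 < t2 <= t1`, within-region splits
#' between `t3` and `t2`, and for scenario 2 an admixture event that
#' postdates the donor region's internal split and predates the
#' recipient's, so the donor is the merged ancestral lineage of the
#' second region) are enforced by rejection-resampling.
#'
#' @param scenario a `demographic_scenario`.
#' @param priors a [prior_spec()].
#' @return named list of parameter values.
#' @export
draw_params <- function(scenario, priors = prior_spec()) {
  t3 <- priors$t3
  repeat {
    ne <- stats::runif(1, priors$ne_range[1], priors$ne_range[2])
    t1 <- stats::runif(1, priors$t1_range[1], priors$t1_range[2])
    t2 <- stats::runif(1, t3 + 1, t1)
    tw1 <- stats::runif(1, t3 + 1, t2)
    tw2 <- stats::runif(1, t3 + 1, t2)
    t4 <- stats::runif(1, t3 + 1, t2)
    t5 <- sample(seq(priors$t5_range[1], priors$t5_range[2]), 1L)
    r <- stats::runif(1, priors$r_range[1], priors$r_range[2])
    mu <- exp(stats::runif(1, log(priors$mu_range[1]),
                           log(priors$mu_range[2])))
    # pre-herbicide admixture flows from the merged TN ancestral lineage
    # into one extant NC population: the event must postdate the TN
    # within-region split and predate the NC one (backward in time)
    if (scenario$admixture == "pre" && !(t4 > tw2 && t4 < tw1)) next
    break
  }
  list(N_e = ne, N_1 = priors$bottleneck_factor * ne, t1 = t1, t2 = t2,
       t3 = t3, t4 = t4, t5 = t5, tw1 = tw1, tw2 = tw2, r = r, mu = mu)
}

# event matrix for the C++ engine: columns (time, type, a, b, x) with
# type 0 = size change, 1 = merge a -> b, 2 = admixture a -> b w.p. x;
# demes 0,1 = region 1, demes 2,3 = region 2
scenario_events <- function(scenario, params) {
  ev <- rbind(
    c(params$t3, 0, -1, 0, params$N_e),
    c(params$tw1, 1, 1, 0, 0),
    c(params$tw2, 1, 3, 2, 0),
    c(params$t2, 1, 2, 0, 0))
  if (scenario$admixture == "pre")
    ev <- rbind(ev, c(params$t4, 2, 0, 2, params$r))
  if (scenario$admixture == "post")
    ev <- rbind(ev, c(params$t5, 2, 0, 2, params$r))
  ev[order(ev[, 1]), , drop = FALSE]
}

#' Simulate SSR genotypes under a demographic scenario
#'
#' Backward-in-time coalescent for the four sampled populations with the
#' scenario's divergence/bottleneck/admixture events, stepwise mutations
#' from a root of 100 repeats (reflecting bounds 50-300).
#'
#' @param scenario a `demographic_scenario`.
#' @param params parameter list from [draw_params()].
#' @param n_ind diploid individuals per population.
#' @param n_loci number of loci.
#' @param seed integer seed, or `NULL` to draw from the current RNG
#'   stream (used inside reference-table construction).
#' @return a [genotype_dataset()].
#' @export
simulate_coalescent_ssr <- function(scenario, params, n_ind = 18L,
                                    n_loci = 15L, seed = 1L) {
  if (!is.null(seed)) set.seed(seed)
  if (params$N_e <= 0 || params$r < 0 || params$r > 1 ||
      params$t2 > params$t1 || params$t5 >= params$t3)
    stop("invalid scenario parameters")
  ev <- scenario_events(scenario, params)
  geno <- cpp_coal_scenario(rep(as.integer(n_ind), 4L),
                            rep(params$N_1, 4L), ev, params$mu,
                            as.integer(n_loci), 100L,
                            SSR_SIZE_MIN, SSR_SIZE_MAX)
  pops <- factor(rep(scenario$pops, each = n_ind),
                 levels = scenario$pops)
  ds <- genotype_dataset(geno, pop = pops)
  attr(ds, "tmrca") <- attr(geno, "tmrca")
  ds
}

#' Summary-statistic vector for ABC
#'
#' Per population: mean number of alleles per locus, mean expected
#' heterozygosity, mean allele-size variance, mean M-ratio (alleles
#' divided by size range + 1).  Per population pair: Weir-Cockerham theta
#' and the mean squared difference in mean allele size (delta-mu
#' squared).  Fixed ordering; length `4P + 2 * P(P-1)/2`.
#'
#' @param ds a [genotype_dataset()] with `>= 2` populations.
#' @return named numeric vector.
#' @export
summary_stats <- function(ds) {
  prep <- pg_prep(ds)
  pop <- as.integer(ds$ind$pop)
  P <- nlevels(ds$ind$pop)
  pops <- populations(ds)
  L <- length(prep)
  k_mat <- he_mat <- v_mat <- m_mat <- matrix(NA_real_, P, L)
  msize <- matrix(NA_real_, P, L)
  cnts <- hets <- nis <- vector("list", L) # per-locus tallies, reused below
  for (l in seq_len(L)) {
    p <- prep[[l]]
    ok <- !is.na(p$a1)
    K <- max(p$K, 1L)
    cnt <- matrix(tabulate(pop[ok] + P * (p$a1[ok] - 1L), P * K) +
                  tabulate(pop[ok] + P * (p$a2[ok] - 1L), P * K), nrow = P)
    hsel <- ok & p$a1 != p$a2
    het <- matrix(tabulate(pop[hsel] + P * (p$a1[hsel] - 1L), P * K) +
                  tabulate(pop[hsel] + P * (p$a2[hsel] - 1L), P * K),
                  nrow = P)
    ni <- tabulate(pop[ok], P)
    cnts[[l]] <- cnt; hets[[l]] <- het; nis[[l]] <- ni
    for (i in which(ni > 0)) {
      k <- sum(cnt[i, ] > 0)
      pr <- cnt[i, ] / (2 * ni[i])
      k_mat[i, l] <- k
      he_mat[i, l] <- 1 - sum(pr^2)
      present <- which(cnt[i, ] > 0)
      sz_range <- p$sizes[range(present)]
      msize[i, l] <- sum(p$sizes * pr)
      v_mat[i, l] <- sum(cnt[i, ] * (p$sizes - msize[i, l])^2) /
        max(1, 2 * ni[i] - 1)
      m_mat[i, l] <- k / (diff(sz_range) + 1)
    }
  }
  out <- c()
  for (i in seq_len(P)) {
    v <- c(mean(k_mat[i, ], na.rm = TRUE), mean(he_mat[i, ], na.rm = TRUE),
           mean(v_mat[i, ], na.rm = TRUE), mean(m_mat[i, ], na.rm = TRUE))
    names(v) <- paste0(c("nall_", "he_", "sizevar_", "mratio_"), pops[i])
    out <- c(out, v)
  }
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    comp <- rowSums(vapply(seq_len(L), function(l)
      wc_abc_from_counts(cnts[[l]][c(i, j), , drop = FALSE],
                         hets[[l]][c(i, j), , drop = FALSE],
                         nis[[l]][c(i, j)]), numeric(3)))
    th <- if (sum(comp) == 0) 0 else comp[1] / sum(comp)
    dmu <- mean((msize[i, ] - msize[j, ])^2, na.rm = TRUE)
    v <- c(th, dmu)
    names(v) <- paste0(c("theta_", "dmu2_"), pops[i], ".", pops[j])
    out <- c(out, v)
  }
  out[!is.finite(out)] <- 0
  out
}

#' Build an ABC reference table
#'
#' For each row: draw parameters from the priors, simulate the scenario,
#' summarize.  Rows are interleaved across scenarios and the whole table
#' is reproducible from the seed.
#'
#' @param scenarios list from [build_scenarios()].
#' @param priors a [prior_spec()].
#' @param n_per_scenario simulations per scenario (values below 1000 are
#'   refused, below 10000 warned: rejection ABC needs a dense table).
#' @param seed integer seed.
#' @param n_ind,n_loci sampling design per simulation.
#' @return `data.frame` of class `abc_reference`: `scenario`, parameter
#'   columns, then summary-statistic columns (attribute `stat_cols`).
#' @export
build_reference_table <- function(scenarios, priors = prior_spec(),
                                  n_per_scenario = 10000L, seed = 1L,
                                  n_ind = 18L, n_loci = 15L) {
  if (n_per_scenario < 1000L)
    stop("n_per_scenario < 1000 is too sparse for rejection ABC")
  if (n_per_scenario < 10000L)
    warning("n_per_scenario < 10000: posterior estimates will be noisy")
  set.seed(seed)
  par_names <- c("N_e", "t1", "t2", "t4", "t5", "tw1", "tw2", "r", "mu")
  rows <- vector("list", 3L * n_per_scenario)
  idx <- 0L
  for (b in seq_len(n_per_scenario)) {
    for (s in seq_along(scenarios)) {
      pars <- draw_params(scenarios[[s]], priors)
      ds <- simulate_coalescent_ssr(scenarios[[s]], pars, n_ind = n_ind,
                                    n_loci = n_loci, seed = NULL)
      idx <- idx + 1L
      rows[[idx]] <- c(scenario = scenarios[[s]]$id,
                       unlist(pars[par_names]), summary_stats(ds))
    }
  }
  tab <- as.data.frame(do.call(rbind, rows))
  attr(tab, "stat_cols") <- setdiff(names(tab), c("scenario", par_names))
  attr(tab, "par_cols") <- par_names
  attr(tab, "design") <- list(n_ind = n_ind, n_loci = n_loci, seed = seed,
                              n_per_scenario = n_per_scenario)
  class(tab) <- c("abc_reference", "data.frame")
  tab
}

#' Write / read a reference table with its metadata sidecar
#'
#' The table is a plain TSV; the sidecar (same path + `.json`) records the
#' design, seed and column roles so a table can be reloaded faithfully.
#'
#' @param ref an `abc_reference`.
#' @param path file path for the TSV.
#' @return `path`, invisibly (writer); the table (reader).
#' @export
write_reference_table <- function(ref, path) {
  utils::write.table(ref, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(stat_cols = attr(ref, "stat_cols"),
               par_cols = attr(ref, "par_cols"),
               design = attr(ref, "design"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  attr(tab, "stat_cols") <- meta$stat_cols
  attr(tab, "par_cols") <- meta$par_cols
  attr(tab, "design") <- meta$design
  class(tab) <- c("abc_reference", "data.frame")
  tab
}

#' ABC model choice: rejection + local logistic regression
#'
#' Summaries are standardized by the reference table's means and SDs;
#' the closest `tolerance` fraction of rows (Euclidean distance to the
#' observed vector) is retained.  The direct estimate is the scenario
#' frequency among retained rows.  For the refined estimate the
#' standardized summaries are first projected onto the linear
#' discriminant axes separating the scenarios (trained on the whole
#' reference table), and a multinomial logistic regression of scenario on
#' (discriminant scores - observed scores), weighted by an Epanechnikov
#' kernel on distance, is evaluated at the observed point; the projection
#' keeps the local regression well-conditioned at small retained counts.
#' CIs come from the regression's asymptotic covariance pushed through
#' the softmax.
#'
#' @param ref an `abc_reference`.
#' @param observed named summary vector from [summary_stats()].
#' @param tolerance fraction of rows to retain (default 0.01).
#' @return list of class `abc_result`: `direct`, `logistic` (each a
#'   probability vector over scenarios summing to 1), `ci` (2 x K),
#'   `n_accepted`, `tolerance`, `note`.
#' @export
abc_model_choice <- function(ref, observed, tolerance = 0.01) {
  if (tolerance <= 0 || tolerance > 1) stop("tolerance must be in (0, 1]")
  stat_cols <- attr(ref, "stat_cols")
  if (!all(stat_cols %in% names(observed)))
    stop("observed vector does not match reference-table columns")
  S <- as.matrix(ref[, stat_cols, drop = FALSE])
  obs <- observed[stat_cols]
  mu <- colMeans(S)
  sdv <- apply(S, 2, stats::sd)
  use <- sdv > 0
  Z <- sweep(sweep(S[, use, drop = FALSE], 2, mu[use]), 2, sdv[use], "/")
  zo <- (obs[use] - mu[use]) / sdv[use]
  d <- sqrt(rowSums(sweep(Z, 2, zo)^2))
  k <- max(3L, ceiling(tolerance * nrow(ref)))
  sel <- order(d)[seq_len(k)]
  scen <- factor(ref$scenario[sel], levels = sort(unique(ref$scenario)))
  K <- nlevels(scen)
  direct <- as.numeric(table(scen)) / k
  names(direct) <- paste0("scenario", levels(scen))
  dmax <- max(d[sel])
  w <- if (dmax > 0) 1 - (d[sel] / dmax)^2 else rep(1, k)
  w <- pmax(w, 1e-8)
  present <- levels(scen)[tabulate(scen, K) > 0]
  note <- if (length(present) < K)
    paste("scenarios absent from retained set:",
          paste(setdiff(levels(scen), present), collapse = ", "))
  else NA_character_
  logistic <- direct
  ci <- matrix(NA_real_, 2, K,
               dimnames = list(c("lower", "upper"), names(direct)))
  if (length(present) >= 2L) {
    proj <- tryCatch(suppressWarnings(
      MASS::lda(Z, grouping = factor(ref$scenario))$scaling),
      error = function(e) NULL)
    X <- if (is.null(proj)) sweep(Z[sel, , drop = FALSE], 2, zo) else
      sweep(Z[sel, , drop = FALSE] %*% proj, 2, drop(zo %*% proj))
    dat <- data.frame(scen = droplevels(scen), X)
    fit <- tryCatch(
      nnet::multinom(scen ~ ., data = dat, weights = w, trace = FALSE,
                     maxit = 500),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                         dimnames = list(
                                           levels(droplevels(scen))[2],
                                           names(cf)))
      eta <- c(0, cf[, "(Intercept)"])
      pr <- exp(eta - max(eta))
      pr <- pr / sum(pr)
      logistic[] <- 0
      logistic[paste0("scenario", levels(droplevels(scen)))] <- pr
      # delta method on the intercepts through the softmax
      V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
      if (!is.null(V)) {
        cn <- colnames(V)
        int_idx <- grep("(Intercept)", cn, fixed = TRUE)
        Vi <- V[int_idx, int_idx, drop = FALSE]
        Kp <- length(pr)
        se <- numeric(Kp)
        for (i in seq_len(Kp)) {
          g <- numeric(Kp - 1) # d p_i / d eta_j, j = 2..Kp
          for (j in 2:Kp)
            g[j - 1] <- pr[i] * ((i == j) - pr[j])
          se[i] <- sqrt(max(0, drop(t(g) %*% Vi %*% g)))
        }
        lv <- paste0("scenario", levels(droplevels(scen)))
        ci["lower", lv] <- pmax(0, pr - 1.96 * se)
        ci["upper", lv] <- pmin(1, pr + 1.96 * se)
        absent <- setdiff(names(direct), lv)
        ci[, absent] <- c(0, 0)
      }
    }
  } else {
    logistic[] <- 0
    logistic[paste0("scenario", present)] <- 1
  }
  structure(list(direct = direct, logistic = logistic, ci = ci,
                 n_accepted = k, tolerance = tolerance, note = note),
            class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf("ABC model choice (tolerance %.3g, %d accepted)\n",
              x$tolerance, x$n_accepted))
  for (i in seq_along(x$logistic))
    cat(sprintf("  %s: logistic %.4f (%.4f..%.4f), direct %.4f\n",
                names(x$logistic)[i], x$logistic[i], x$ci[1, i],
                x$ci[2, i], x$direct[i]))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Confusion matrix for ABC scenario choice
#'
#' Pseudo-observed datasets are drawn from the priors under each true
#' scenario and classified by the argmax of the logistic posterior; rows
#' (true scenario) are normalized to sum to 1.
#'
#' @param ref an `abc_reference`.
#' @param scenarios list from [build_scenarios()].
#' @param priors a [prior_spec()].
#' @param n_pods pseudo-observed datasets per scenario.
#' @param tolerance retained fraction for each model choice.
#' @param seed integer seed (kept distinct from the table's seed).
#' @return 3 x 3 matrix of recovery rates.
#' @export
confusion_matrix <- function(ref, scenarios, priors = prior_spec(),
                             n_pods = 50L, tolerance = 0.01, seed = 2L) {
  design <- attr(ref, "design")
  set.seed(seed)
  K <- length(scenarios)
  cm <- matrix(0, K, K,
               dimnames = list(paste0("true", seq_len(K)),
                               paste0("chosen", seq_len(K))))
  for (s in seq_len(K)) {
    for (b in seq_len(n_pods)) {
      pars <- draw_params(scenarios[[s]], priors)
      ds <- simulate_coalescent_ssr(scenarios[[s]], pars,
                                    n_ind = design$n_ind,
                                    n_loci = design$n_loci, seed = NULL)
      res <- abc_model_choice(ref, summary_stats(ds), tolerance)
      pick <- which.max(res$logistic)
      cm[s, pick] <- cm[s, pick] + 1
    }
  }
  cm / n_pods
}
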