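## Microsatellite diversity, quality control and differentiation statistics.
## All estimators use pairwise-complete data per locus: an individual
## missing at a locus is excluded from that locus only.

# integer-coded per-locus view used by every estimator (internal):
# list per locus with a1/a2 allele indices 1..K (NA = missing), sizes =
# original allele sizes per index
pg_prep <- function(ds) {
  lapply(seq_along(ds$loci), function(l) {
    m <- locus_alleles(ds, l)
    sizes <- sort(unique(m[!is.na(m)]))
    list(a1 = match(m[, 1], sizes), a2 = match(m[, 2], sizes),
         K = length(sizes), sizes = sizes)
  })
}

#' Per-population allele frequencies
#'
#' @param ds a [genotype_dataset()]
#' @return list with `freq` (per locus, a populations x alleles matrix of
#'   frequencies over non-missing calls), `n` (populations x loci matrix of
#'   genotyped individuals), and `empty` (logical matrix flagging cells
#'   with no calls).
#' @export
allele_frequencies <- function(ds) {
  prep <- pg_prep(ds)
  pop <- as.integer(ds$ind$pop)
  r <- nlevels(ds$ind$pop)
  freq <- vector("list", length(ds$loci))
  names(freq) <- ds$loci
  nmat <- matrix(0L, r, length(ds$loci),
                 dimnames = list(populations(ds), ds$loci))
  for (l in seq_along(prep)) {
    p <- prep[[l]]
    ok <- !is.na(p$a1)
    cnt <- matrix(tabulate(pop[ok] + r * (p$a1[ok] - 1L), r * max(p$K, 1L)) +
                  tabulate(pop[ok] + r * (p$a2[ok] - 1L), r * max(p$K, 1L)),
                  nrow = r)
    nmat[, l] <- tabulate(pop[ok], r)
    f <- cnt / pmax(2L * nmat[, l], 1L)
    dimnames(f) <- list(populations(ds), p$sizes)
    freq[[l]] <- f
  }
  list(freq = freq, n = nmat, empty = nmat == 0L)
}

#' Genetic diversity per population and locus
#'
#' Expected heterozygosity `H_e = 1 - sum p^2` (optionally with the
#' small-sample factor `2n/(2n-1)`), observed heterozygosity, allele
#' counts, and rarefied allelic richness at a standardized number of genes
#' `g` by the hypergeometric expectation
#' `sum_a (1 - choose(2n - c_a, g) / choose(2n, g))`.
#'
#' @param ds a [genotype_dataset()]
#' @param g number of genes for rarefaction (default the smallest `2n`
#'   over non-empty cells); cells with `2n < g` are skipped and flagged.
#' @param unbiased apply the `2n/(2n-1)` correction to `H_e`.
#' @return `data.frame` with one row per population x locus.
#' @export
diversity <- function(ds, g = NULL, unbiased = FALSE) {
  prep <- pg_prep(ds)
  pop <- as.integer(ds$ind$pop)
  r <- nlevels(ds$ind$pop)
  if (is.null(g)) {
    nmin <- Inf
    for (l in seq_along(prep)) {
      ok <- !is.na(prep[[l]]$a1)
      nn <- tabulate(pop[ok], r)
      nmin <- min(nmin, nn[nn > 0])
    }
    g <- 2L * nmin
  }
  out <- list()
  for (l in seq_along(prep)) {
    p <- prep[[l]]
    ok <- !is.na(p$a1)
    for (i in seq_len(r)) {
      sel <- ok & pop == i
      n <- sum(sel)
      if (n == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          population = populations(ds)[i], locus = ds$loci[l], n = 0L,
          k = NA_integer_, richness = NA_real_, He = NA_real_,
          Ho = NA_real_, skipped = TRUE)
        next
      }
      cnt <- tabulate(c(p$a1[sel], p$a2[sel]), p$K)
      pr <- cnt / (2 * n)
      he <- 1 - sum(pr^2)
      if (unbiased) he <- he * 2 * n / (2 * n - 1)
      rich <- if (g > 2 * n) NA_real_ else
        sum(1 - exp(lchoose(2 * n - cnt, g) - lchoose(2 * n, g)))
      out[[length(out) + 1L]] <- data.frame(
        population = populations(ds)[i], locus = ds$loci[l], n = n,
        k = sum(cnt > 0), richness = rich, He = he,
        Ho = mean(p$a1[sel] != p$a2[sel]), skipped = is.na(rich))
    }
  }
  res <- do.call(rbind, out)
  attr(res, "g") <- g
  res
}

## ---- Hardy-Weinberg exact test (Levene conditional distribution) -------

# all genotype configurations for <= 3 alleles, with Levene log-probability
hwe_enumerate <- function(gcounts) {
  # gcounts: K x K upper-triangular genotype count matrix (observed)
  K <- nrow(gcounts)
  acount <- integer(K)
  for (i in seq_len(K)) for (j in i:K) {
    acount[i] <- acount[i] + gcounts[i, j]
    acount[j] <- acount[j] + gcounts[i, j]
  }
  n <- sum(gcounts)
  logc <- lfactorial(n) + sum(lfactorial(acount)) - lfactorial(2 * n)
  logp_config <- function(g) {
    H <- sum(g[upper.tri(g)])
    logc + H * log(2) - sum(lfactorial(g[upper.tri(g, diag = TRUE)]))
  }
  configs <- list()
  if (K == 1L) {
    configs[[1]] <- gcounts
  } else if (K == 2L) {
    for (h in seq(acount[1] %% 2L, min(acount[1], acount[2]), by = 2L)) {
      g <- matrix(0L, 2, 2)
      g[1, 2] <- h
      g[1, 1] <- (acount[1] - h) %/% 2L
      g[2, 2] <- (acount[2] - h) %/% 2L
      configs[[length(configs) + 1L]] <- g
    }
  } else if (K == 3L) {
    for (h12 in 0:min(acount[1], acount[2]))
      for (h13 in 0:min(acount[1] - h12, acount[3]))
        for (h23 in 0:min(acount[2] - h12, acount[3] - h13)) {
          r1 <- acount[1] - h12 - h13
          r2 <- acount[2] - h12 - h23
          r3 <- acount[3] - h13 - h23
          if (r1 < 0 || r2 < 0 || r3 < 0) next
          if (r1 %% 2L || r2 %% 2L || r3 %% 2L) next
          g <- matrix(0L, 3, 3)
          g[1, 2] <- h12; g[1, 3] <- h13; g[2, 3] <- h23
          diag(g) <- c(r1, r2, r3) %/% 2L
          configs[[length(configs) + 1L]] <- g
        }
  } else stop("enumeration supports <= 3 alleles")
  lp <- vapply(configs, logp_config, numeric(1))
  lp_obs <- logp_config(gcounts)
  sum(exp(lp[lp <= lp_obs + 1e-9]))
}

#' Exact Hardy-Weinberg test for one locus in one population
#'
#' The probability test: conditional on the observed allele counts
#' (Levene's distribution), the p-value is the total probability of
#' genotype configurations no more probable than the observed one.  Full
#' enumeration is used for up to 3 alleles and `n <= 50`; otherwise the
#' conditional distribution is sampled by Monte-Carlo shuffling of allele
#' copies.
#'
#' @param ds a [genotype_dataset()]
#' @param locus locus name or index.
#' @param pop population ID or index.
#' @param method `"auto"`, `"enumerate"` or `"mc"`.
#' @param mc_reps Monte-Carlo replicates (default 100000).
#' @param seed integer seed (Monte-Carlo only).
#' @return the p-value (1 for monomorphic or nearly empty cells).
#' @export
hwe_exact <- function(ds, locus, pop, method = c("auto", "enumerate", "mc"),
                      mc_reps = 100000L, seed = 1L) {
  method <- match.arg(method)
  l <- if (is.character(locus)) match(locus, ds$loci) else as.integer(locus)
  pi <- if (is.character(pop)) match(pop, populations(ds)) else
    as.integer(pop)
  m <- locus_alleles(ds, l)
  sel <- as.integer(ds$ind$pop) == pi & !is.na(m[, 1])
  if (sum(sel) < 2L) return(1)
  sizes <- sort(unique(c(m[sel, 1], m[sel, 2])))
  K <- length(sizes)
  if (K < 2L) return(1)
  a1 <- match(m[sel, 1], sizes); a2 <- match(m[sel, 2], sizes)
  if (method == "auto")
    method <- if (K <= 3L && sum(sel) <= 50L) "enumerate" else "mc"
  if (method == "enumerate") {
    g <- matrix(0L, K, K)
    lo <- pmin(a1, a2); hi <- pmax(a1, a2)
    for (i in seq_along(lo)) g[lo[i], hi[i]] <- g[lo[i], hi[i]] + 1L
    p <- hwe_enumerate(g)
    return(min(p, 1))
  }
  set.seed(seed)
  cpp_hwe_mc(as.integer(as.vector(rbind(a1, a2))), K, as.integer(mc_reps))
}

#' Genotypic linkage-disequilibrium permutation test for a locus pair
#'
#' Log-likelihood-ratio (G) statistic on the two-locus genotype
#' contingency table within one population; significance by permuting the
#' single-locus genotypes of one locus among individuals.
#'
#' @param ds a [genotype_dataset()]
#' @param locusA,locusB locus names or indices.
#' @param pop population ID or index.
#' @param n_perm permutation replicates (default 10000).
#' @param seed integer seed.
#' @return the permutation p-value (1 if either locus is monomorphic).
#' @export
ld_genotypic <- function(ds, locusA, locusB, pop, n_perm = 10000L,
                         seed = 1L) {
  la <- if (is.character(locusA)) match(locusA, ds$loci) else
    as.integer(locusA)
  lb <- if (is.character(locusB)) match(locusB, ds$loci) else
    as.integer(locusB)
  pi <- if (is.character(pop)) match(pop, populations(ds)) else
    as.integer(pop)
  ma <- locus_alleles(ds, la); mb <- locus_alleles(ds, lb)
  sel <- as.integer(ds$ind$pop) == pi & !is.na(ma[, 1]) & !is.na(mb[, 1])
  if (sum(sel) < 2L) return(1)
  ga <- paste(pmin(ma[sel, 1], ma[sel, 2]), pmax(ma[sel, 1], ma[sel, 2]))
  gb <- paste(pmin(mb[sel, 1], mb[sel, 2]), pmax(mb[sel, 1], mb[sel, 2]))
  if (length(unique(ga)) < 2L || length(unique(gb)) < 2L) return(1)
  gstat <- function(x, y) {
    tab <- table(x, y)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    o <- tab[tab > 0]
    2 * sum(o * log(o / e[tab > 0]))
  }
  g_obs <- gstat(ga, gb)
  set.seed(seed)
  cnt <- 0L
  for (i in seq_len(n_perm))
    if (gstat(ga, sample(gb)) >= g_obs - 1e-9) cnt <- cnt + 1L
  (1 + cnt) / (1 + n_perm)
}

#' Fisher's method for combining independent p-values
#'
#' `X = -2 sum ln p` is chi-squared with `2k` degrees of freedom under the
#' global null.
#'
#' @param p_list vector of p-values in `[0, 1]`.
#' @return the combined p-value.
#' @export
fisher_combine <- function(p_list) {
  p_list <- p_list[!is.na(p_list)]
  if (!length(p_list)) return(NA_real_)
  x <- -2 * sum(log(pmax(p_list, .Machine$double.xmin)))
  stats::pchisq(x, df = 2 * length(p_list), lower.tail = FALSE)
}

#' Sequential Bonferroni (Holm step-down) correction
#'
#' @param p_list p-values.
#' @param alpha family-wise error level.
#' @return list with `adjusted` (Holm-adjusted p, via [stats::p.adjust()])
#'   and `reject` (logical decisions at `alpha`).
#' @export
holm_correction <- function(p_list, alpha = 0.05) {
  adj <- stats::p.adjust(p_list, method = "holm")
  list(adjusted = adj, reject = adj <= alpha)
}

## ---- Weir & Cockerham theta --------------------------------------------

# per-locus variance components a (among pops), b (among individuals
# within), c (within individuals), summed over alleles; zero vector when
# the locus is unusable (monomorphic, < 2 populations with data)
wc_abc_locus <- function(a1, a2, pop, r) {
  ok <- !is.na(a1)
  if (!any(ok)) return(c(0, 0, 0))
  a1 <- a1[ok]; a2 <- a2[ok]; p <- pop[ok]
  ni_all <- tabulate(p, r)
  use <- ni_all > 0L
  rr <- sum(use)
  if (rr < 2L) return(c(0, 0, 0))
  K <- max(a1, a2)
  if (K < 2L) return(c(0, 0, 0))
  cnt <- matrix(tabulate(p + r * (a1 - 1L), r * K) +
                tabulate(p + r * (a2 - 1L), r * K), nrow = r)[use, ,
                                                              drop = FALSE]
  het <- a1 != a2
  hcnt <- matrix(tabulate(p[het] + r * (a1[het] - 1L), r * K) +
                 tabulate(p[het] + r * (a2[het] - 1L), r * K),
                 nrow = r)[use, , drop = FALSE]
  ni <- ni_all[use]
  ntot <- sum(ni)
  nbar <- ntot / rr
  if (nbar <= 1) return(c(0, 0, 0))
  nc <- (ntot - sum(ni^2) / ntot) / (rr - 1)
  if (nc <= 0) return(c(0, 0, 0))
  piu <- cnt / (2 * ni)
  pbar <- colSums(cnt) / (2 * ntot)
  dev <- piu - matrix(pbar, rr, K, byrow = TRUE)
  s2 <- colSums(ni * dev^2) / ((rr - 1) * nbar)
  hbar <- colSums(hcnt) / ntot
  inner <- pbar * (1 - pbar) - (rr - 1) / rr * s2
  a_u <- nbar / nc * (s2 - (inner - hbar / 4) / (nbar - 1))
  b_u <- nbar / (nbar - 1) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_u <- hbar / 2
  c(sum(a_u), sum(b_u), sum(c_u))
}

# WC components from precomputed per-population allele counts (cnt),
# heterozygote-carriage counts (hcnt) and sample sizes (ni); rows = pops
wc_abc_from_counts <- function(cnt, hcnt, ni) {
  use <- ni > 0
  rr <- sum(use)
  if (rr < 2L) return(c(0, 0, 0))
  cnt <- cnt[use, , drop = FALSE]
  hcnt <- hcnt[use, , drop = FALSE]
  ni <- ni[use]
  ntot <- sum(ni)
  nbar <- ntot / rr
  if (nbar <= 1) return(c(0, 0, 0))
  nc <- (ntot - sum(ni^2) / ntot) / (rr - 1)
  if (nc <= 0) return(c(0, 0, 0))
  K <- ncol(cnt)
  piu <- cnt / (2 * ni)
  pbar <- colSums(cnt) / (2 * ntot)
  dev <- piu - matrix(pbar, rr, K, byrow = TRUE)
  s2 <- colSums(ni * dev^2) / ((rr - 1) * nbar)
  hbar <- colSums(hcnt) / ntot
  inner <- pbar * (1 - pbar) - (rr - 1) / rr * s2
  a_u <- nbar / nc * (s2 - (inner - hbar / 4) / (nbar - 1))
  b_u <- nbar / (nbar - 1) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_u <- hbar / 2
  c(sum(a_u), sum(b_u), sum(c_u))
}

wc_components <- function(prep, pop, r) {
  t(vapply(prep, function(p) wc_abc_locus(p$a1, p$a2, pop, r), numeric(3)))
}

theta_from_comp <- function(comp) {
  den <- sum(comp)
  if (den == 0) return(NA_real_)
  sum(comp[, 1]) / den
}

#' Weir-Cockerham theta (F_ST) with jackknife CI and permutation test
#'
#' Variance-component estimator of Weir & Cockerham (1984) for unequal
#' sample sizes: per locus and allele, components among populations (a),
#' among individuals within populations (b) and within individuals (c);
#' `theta = sum a / sum (a + b + c)` over alleles and loci.  The 95% CI is
#' a delete-one-locus jackknife; significance comes from permuting whole
#' multilocus genotypes among populations.
#'
#' @param ds a [genotype_dataset()] with `>= 2` populations.
#' @param n_perm permutations for the p-value (0 skips the test).
#' @param seed integer seed.
#' @return list of class `theta_result`: `theta`, `per_locus`, `se`,
#'   `ci` (jackknife), `p` (permutation, or `NA`), `n_perm`.
#' @export
wc_theta <- function(ds, n_perm = 0L, seed = 1L) {
  r <- nlevels(ds$ind$pop)
  if (r < 2L) stop("need >= 2 populations")
  prep <- pg_prep(ds)
  pop <- as.integer(ds$ind$pop)
  comp <- wc_components(prep, pop, r)
  theta <- theta_from_comp(comp)
  if (is.na(theta)) stop("theta undefined: no usable variation")
  L <- nrow(comp)
  per_locus <- ifelse(rowSums(comp) == 0, NA_real_,
                      comp[, 1] / rowSums(comp))
  usable <- which(rowSums(comp) != 0)
  se <- NA_real_; ci <- c(NA_real_, NA_real_)
  if (length(usable) >= 2L) {
    jack <- vapply(usable, function(l)
      theta_from_comp(comp[-l, , drop = FALSE]), numeric(1))
    Lu <- length(usable)
    se <- sqrt((Lu - 1) / Lu * sum((jack - mean(jack))^2))
    ci <- theta + c(-1, 1) * 1.96 * se
  }
  p <- NA_real_
  if (n_perm > 0L) {
    set.seed(seed)
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      tp <- theta_from_comp(wc_components(prep, sample(pop), r))
      if (!is.na(tp) && tp >= theta - 1e-12) cnt <- cnt + 1L
    }
    p <- (1 + cnt) / (1 + n_perm)
  }
  structure(list(theta = theta, per_locus = per_locus, se = se, ci = ci,
                 p = p, n_perm = as.integer(n_perm)),
            class = "theta_result")
}

#' @export
print.theta_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham theta = %.4f (jackknife 95%% CI %.4f..%.4f)",
              x$theta, x$ci[1], x$ci[2]))
  if (!is.na(x$p)) cat(sprintf(", permutation p = %.4g", x$p))
  cat("\n")
  invisible(x)
}

#' Pairwise F_ST matrix with permutation tests and Holm correction
#'
#' Weir-Cockerham theta for every population pair; per-pair significance
#' by permuting individuals between the two populations, family-wise
#' control across all pairs by Holm step-down.  The diagonal is 0 by
#' convention.
#'
#' @param ds a [genotype_dataset()]
#' @param n_perm permutations per pair (0 skips the tests).
#' @param seed integer seed.
#' @return list: `fst` (symmetric matrix), `p` (raw permutation p),
#'   `p_adj` (Holm), `significant` (logical at `alpha`), `alpha`.
#' @export
pairwise_fst_matrix <- function(ds, n_perm = 0L, seed = 1L, alpha = 0.05) {
  pops <- populations(ds)
  r <- length(pops)
  prep <- pg_prep(ds)
  pop <- as.integer(ds$ind$pop)
  fst <- matrix(0, r, r, dimnames = list(pops, pops))
  pmat <- matrix(NA_real_, r, r, dimnames = list(pops, pops))
  set.seed(seed)
  for (i in seq_len(r - 1)) for (j in (i + 1):r) {
    sel <- which(pop == i | pop == j)
    sub_pop <- ifelse(pop[sel] == i, 1L, 2L)
    sub_prep <- lapply(prep, function(p)
      list(a1 = p$a1[sel], a2 = p$a2[sel], K = p$K))
    comp <- wc_components(sub_prep, sub_pop, 2L)
    th <- theta_from_comp(comp)
    fst[i, j] <- fst[j, i] <- th
    if (is.na(th)) next
    if (n_perm > 0L) {
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        tp <- theta_from_comp(wc_components(sub_prep, sample(sub_pop), 2L))
        if (!is.na(tp) && tp >= th - 1e-12) cnt <- cnt + 1L
      }
      pmat[i, j] <- pmat[j, i] <- (1 + cnt) / (1 + n_perm)
    }
  }
  ut <- upper.tri(pmat)
  p_adj <- sig <- matrix(NA_real_, r, r, dimnames = list(pops, pops))
  if (n_perm > 0L) {
    hc <- holm_correction(pmat[ut], alpha)
    p_adj[ut] <- hc$adjusted
    p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
    sig <- p_adj <= alpha
  }
  list(fst = fst, p = pmat, p_adj = p_adj, significant = sig,
       alpha = alpha)
}

## ---- R_ST ---------------------------------------------------------------

rst_locus <- function(a1, a2, pop, r, sizes) {
  ok <- !is.na(a1)
  if (!any(ok)) return(c(NA, NA))
  y <- c(sizes[a1[ok]], sizes[a2[ok]])
  g <- c(pop[ok], pop[ok])
  ni <- tabulate(g, r)
  use <- ni > 0
  rr <- sum(use)
  if (rr < 2L || length(unique(y)) < 2L) return(c(NA, NA))
  ntot <- length(y)
  gm <- mean(y)
  means <- vapply(which(use), function(i) mean(y[g == i]), numeric(1))
  ni <- ni[use]
  ss_among <- sum(ni * (means - gm)^2)
  ss_within <- sum((y - means[match(g, which(use))])^2)
  ms_a <- ss_among / (rr - 1)
  ms_w <- ss_within / (ntot - rr)
  n0 <- (ntot - sum(ni^2) / ntot) / (rr - 1)
  c(a = (ms_a - ms_w) / n0, w = ms_w)
}

#' R_ST: differentiation from allele-size variance (stepwise mutation)
#'
#' AMOVA-style two-level variance-component estimator on allele sizes:
#' among-population versus within-population allele-size variance, summed
#' over loci, with a delete-one-locus jackknife CI.
#'
#' @param ds a [genotype_dataset()]
#' @return list of class `rst_result`: `rst`, `per_locus`, `se`, `ci`.
#' @export
rst <- function(ds) {
  r <- nlevels(ds$ind$pop)
  if (r < 2L) stop("need >= 2 populations")
  prep <- pg_prep(ds)
  pop <- as.integer(ds$ind$pop)
  comp <- t(vapply(prep, function(p)
    rst_locus(p$a1, p$a2, pop, r, p$sizes), numeric(2)))
  usable <- which(stats::complete.cases(comp))
  if (!length(usable)) stop("R_ST undefined: all loci monomorphic")
  rst_from <- function(cc) sum(cc[, 1]) / sum(cc)
  point <- rst_from(comp[usable, , drop = FALSE])
  per_locus <- rep(NA_real_, nrow(comp))
  per_locus[usable] <- comp[usable, 1] / rowSums(comp[usable, ,
                                                      drop = FALSE])
  se <- NA_real_; ci <- c(NA_real_, NA_real_)
  if (length(usable) >= 2L) {
    jack <- vapply(seq_along(usable), function(i)
      rst_from(comp[usable[-i], , drop = FALSE]), numeric(1))
    Lu <- length(usable)
    se <- sqrt((Lu - 1) / Lu * sum((jack - mean(jack))^2))
    ci <- point + c(-1, 1) * 1.96 * se
  }
  structure(list(rst = point, per_locus = per_locus, se = se, ci = ci),
            class = "rst_result")
}

## ---- hierarchical AMOVA -------------------------------------------------

# within-group sum of squares at one grouping, allele-identity metric:
# (1/2) sum_g (n_g - sum_u c_gu^2 / n_g); `grp` integer per copy
amova_wss <- function(allele, grp, ngrp, K) {
  cnt <- matrix(tabulate(grp + ngrp * (allele - 1L), ngrp * K), nrow = ngrp)
  ng <- tabulate(grp, ngrp)
  nz <- ng > 0
  sum(ng[nz] - rowSums(cnt[nz, , drop = FALSE]^2) / ng[nz]) / 2
}

# T statistic of the expected-SS linear system: cells of a component
# nested in groups of a level -> sum over cells n_cell^2 / n_group(cell)
amova_T <- function(n_cell, cell2grp, n_grp) {
  sum(n_cell^2 / n_grp[cell2grp])
}

# Variance components for one locus given nested grouping vectors per
# allele copy (list coarse -> fine, excluding the per-copy level).
# Method of moments: observed stratum SS are equated to their expectations
# E[SS] = sum_c sigma2_c (T_c(level) - T_c(parent)), where for component c
# with cells nested inside the groups of a level,
# T_c(level) = sum_cells n_cell^2 / n_group(cell); a component coarser
# than (or equal to) the level has T = N.  This is exact for unequal
# sample sizes and reduces to the textbook nested-ANOVA coefficients when
# the design is balanced.
amova_locus <- function(allele, K, levels_list) {
  N <- length(allele)
  q <- length(levels_list)
  ngrp <- vapply(levels_list, max, integer(1))
  W <- numeric(q + 1L) # within-group SS at total, then at each level
  W[1] <- amova_wss(allele, rep(1L, N), 1L, K)
  for (k in seq_len(q))
    W[k + 1L] <- amova_wss(allele, levels_list[[k]], ngrp[k], K)
  SS <- c(-diff(W), W[q + 1L]) # among each level, then within finest
  sizes <- lapply(levels_list, function(g) tabulate(g, max(g)))
  Tval <- function(c_idx, L_idx) {
    # c_idx in 1..(q+1) (q+1 = per-copy cells); L_idx in 0..q (0 = total)
    if (c_idx <= L_idx) return(N)
    if (c_idx == q + 1L) { # per-copy cells, all of size 1
      if (L_idx == 0L) return(1)
      return(sum(sizes[[L_idx]] > 0))
    }
    if (L_idx == 0L) return(sum(sizes[[c_idx]]^2) / N)
    cell2grp <- levels_list[[L_idx]][match(seq_len(ngrp[c_idx]),
                                           levels_list[[c_idx]])]
    amova_T(sizes[[c_idx]], cell2grp, sizes[[L_idx]])
  }
  M <- matrix(0, q + 1L, q + 1L)
  for (row in seq_len(q))
    for (cc in seq_len(q + 1L))
      M[row, cc] <- Tval(cc, row) - Tval(cc, row - 1L)
  for (cc in seq_len(q + 1L))
    M[q + 1L, cc] <- N - Tval(cc, q)
  sigma <- tryCatch(solve(M, SS), error = function(e) rep(NA_real_, q + 1L))
  list(sigma = sigma, SS = SS)
}

#' Hierarchical AMOVA (region / state / population / individual)
#'
#' Four-level analysis of molecular variance on the allele-identity
#' (F_ST-analogue) metric: variance components among regions, among
#' states within regions, among populations within states, among
#' individuals within populations, and within individuals, summed over
#' loci, with the F-statistics
#' `F_RT`, `F_SR`, `F_PS`, `F_IT` formed after truncating negative
#' components to zero.  Permutation tests move whole populations among
#' regions (F_RT), populations among states within regions (F_SR),
#' individuals among populations within states (F_PS) and allele copies
#' among individuals within populations (F_IT).
#'
#' @param ds a [genotype_dataset()] with attached metadata (state,
#'   region); with a single region the region level is dropped.
#' @param n_perm permutations per test (0 skips the tests).
#' @param seed integer seed.
#' @return list of class `amova_result`: `sigma` (raw components per
#'   level), `F` (named vector `F_RT`, `F_SR`, `F_PS`, `F_IT`), `p`
#'   (permutation p per F).
#' @export
amova <- function(ds, n_perm = 0L, seed = 1L) {
  if (is.null(ds$meta)) stop("amova needs attached metadata (state/region)")
  pops <- populations(ds)
  meta <- ds$meta[match(pops, ds$meta$population), ]
  prep <- pg_prep(ds)
  pop_of_ind <- as.integer(ds$ind$pop)

  region_of_pop <- factor(meta$region)
  state_of_pop <- factor(paste(meta$region, meta$state, sep = ":"))

  # per-copy grouping builder given (region/state assignment of pops,
  # pop assignment of individuals, copy->individual shuffling per locus).
  # Degenerate levels (a level that does not refine its parent, e.g. a
  # single region, or one population per state) are dropped per locus, so
  # only the remaining levels receive components.
  components <- function(region_of_pop_i, state_of_pop_i, pop_of_ind_i,
                         copy_perm = NULL) {
    sig <- c(region = 0, state = 0, population = 0, individual = 0,
             within = 0)
    seen <- c(region = FALSE, state = FALSE, population = FALSE,
              individual = FALSE, within = FALSE)
    any_locus <- FALSE
    for (l in seq_along(prep)) {
      p <- prep[[l]]
      ok <- which(!is.na(p$a1))
      if (!length(ok)) next
      allele <- c(p$a1[ok], p$a2[ok])
      ind_c <- c(ok, ok)
      if (!is.null(copy_perm)) {
        # shuffle allele copies among individuals within populations
        for (pp in unique(pop_of_ind_i[ok])) {
          idx <- which(pop_of_ind_i[ind_c] == pp)
          allele[idx] <- allele[idx][copy_perm[[l]][[as.character(pp)]]]
        }
      }
      pop_c <- pop_of_ind_i[ind_c]
      lv_all <- list(region = as.integer(region_of_pop_i)[pop_c],
                     state = as.integer(state_of_pop_i)[pop_c],
                     population = pop_c,
                     individual = match(ind_c, ok))
      lv_all <- lapply(lv_all, function(g) as.integer(factor(g)))
      counts <- vapply(lv_all, max, integer(1))
      keep <- logical(4)
      last <- 1L
      for (k in 1:4) {
        if (counts[k] > last) { keep[k] <- TRUE; last <- counts[k] }
      }
      if (!any(keep)) next
      res <- amova_locus(allele, p$K, lv_all[keep])
      if (anyNA(res$sigma)) next
      labs <- c(names(lv_all)[keep], "within")
      sig[labs] <- sig[labs] + res$sigma
      seen[labs] <- TRUE
      any_locus <- TRUE
    }
    if (!any_locus) return(NULL)
    sig[!seen] <- NA_real_
    sig
  }
  f_from <- function(sg) {
    if (is.null(sg)) return(c(F_RT = NA_real_, F_SR = NA_real_,
                              F_PS = NA_real_, F_IT = NA_real_))
    s <- pmax(sg, 0)
    tot <- sum(s, na.rm = TRUE)
    i <- function(nm) if (!is.na(s[[nm]])) s[[nm]] else 0
    c(F_RT = if (is.na(s[["region"]])) NA_real_ else s[["region"]] / tot,
      F_SR = if (is.na(s[["state"]])) NA_real_ else
        s[["state"]] / (tot - i("region")),
      F_PS = if (is.na(s[["population"]])) NA_real_ else
        s[["population"]] / (i("population") + i("individual") +
                               i("within")),
      F_IT = (tot - i("within")) / tot)
  }
  sig <- components(region_of_pop, state_of_pop, pop_of_ind)
  if (is.null(sig)) stop("AMOVA undefined: no usable loci")
  Fs <- f_from(sig)

  pvals <- c(F_RT = NA_real_, F_SR = NA_real_, F_PS = NA_real_,
             F_IT = NA_real_)
  if (n_perm > 0L) {
    set.seed(seed)
    cnt <- c(F_RT = 0L, F_SR = 0L, F_PS = 0L, F_IT = 0L)
    npop <- length(pops)
    for (b in seq_len(n_perm)) {
      if (!is.na(Fs["F_RT"])) { # whole populations among regions
        rp <- region_of_pop[sample(npop)]
        sp <- factor(paste(rp, meta$state, sep = ":"))
        f <- f_from(components(rp, sp, pop_of_ind))
        if (!is.na(f["F_RT"]) && f["F_RT"] >= Fs["F_RT"] - 1e-12)
          cnt["F_RT"] <- cnt["F_RT"] + 1L
      }
      if (!is.na(Fs["F_SR"])) { # populations among states within regions
        sp2 <- state_of_pop
        for (rg in levels(region_of_pop)) {
          idx <- which(meta$region == rg)
          sp2[idx] <- sp2[idx][sample(length(idx))]
        }
        f <- f_from(components(region_of_pop, sp2, pop_of_ind))
        if (!is.na(f["F_SR"]) && f["F_SR"] >= Fs["F_SR"] - 1e-12)
          cnt["F_SR"] <- cnt["F_SR"] + 1L
      }
      if (!is.na(Fs["F_PS"])) { # individuals among pops within states
        po2 <- pop_of_ind
        for (st in levels(state_of_pop)) {
          idx <- which(state_of_pop[pop_of_ind] == st)
          po2[idx] <- po2[idx][sample(length(idx))]
        }
        f <- f_from(components(region_of_pop, state_of_pop, po2))
        if (!is.na(f["F_PS"]) && f["F_PS"] >= Fs["F_PS"] - 1e-12)
          cnt["F_PS"] <- cnt["F_PS"] + 1L
      }
      # allele copies among individuals within populations
      cp <- lapply(seq_along(prep), function(l) {
        p <- prep[[l]]
        ok <- which(!is.na(p$a1))
        out <- list()
        for (pp in unique(pop_of_ind[ok])) {
          sz <- sum(pop_of_ind[c(ok, ok)] == pp)
          out[[as.character(pp)]] <- sample(sz)
        }
        out
      })
      f <- f_from(components(region_of_pop, state_of_pop, pop_of_ind,
                             copy_perm = cp))
      if (!is.na(f["F_IT"]) && f["F_IT"] >= Fs["F_IT"] - 1e-12)
        cnt["F_IT"] <- cnt["F_IT"] + 1L
    }
    pvals <- (1 + cnt) / (1 + n_perm)
    pvals[is.na(Fs)] <- NA_real_
  }
  sig <- sig[!is.na(sig)]
  structure(list(sigma = sig, F = Fs, p = pvals,
                 n_perm = as.integer(n_perm)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Hierarchical AMOVA (allele-identity metric)\n")
  df <- data.frame(component = names(x$sigma), sigma2 = unname(x$sigma))
  print(df, row.names = FALSE)
  for (nm in names(x$F))
    if (!is.na(x$F[nm]))
      cat(sprintf("  %s = %.4f%s\n", nm, x$F[nm],
                  if (!is.na(x$p[nm])) sprintf(" (p = %.4g)", x$p[nm])
                  else ""))
  invisible(x)
}

## ---- null alleles -------------------------------------------------------

# EM for one population x locus: visible allele counts from apparent
# genotypes, missing genotypes treated as null homozygotes
null_em_cell <- function(hom_counts, het_total_per_allele, n_miss,
                         max_iter = 1000L, tol = 1e-10) {
  # hom_counts: apparent homozygote count per visible allele
  # het_total_per_allele: copies of each allele seen in heterozygotes
  K <- length(hom_counts)
  n <- sum(hom_counts) + sum(het_total_per_allele) / 2 + n_miss
  if (n == 0) return(list(r0 = NA_real_, iter = 0L, loglik = NA_real_,
                          converged = FALSE))
  cnt0 <- 2 * hom_counts + het_total_per_allele
  p <- cnt0 / sum(cnt0) * 0.95
  pn <- 0.05
  ll_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- p^2 / (p^2 + 2 * p * pn) # P(true hom | apparent hom)
    w[!is.finite(w)] <- 1
    exp_null_from_hom <- sum(hom_counts * (1 - w))
    copies <- 2 * hom_counts * w + hom_counts * (1 - w) +
      het_total_per_allele
    null_copies <- exp_null_from_hom + 2 * n_miss
    tot <- sum(copies) + null_copies
    p_new <- copies / tot
    pn_new <- null_copies / tot
    ll <- sum(hom_counts * log(pmax(p_new^2 + 2 * p_new * pn_new,
                                    1e-300))) +
      sum(het_total_per_allele / 2 * log(2)) + # constant-ish; kept for monotone trace
      sum(het_total_per_allele * log(pmax(p_new, 1e-300))) +
      n_miss * log(max(pn_new^2, 1e-300))
    delta_par <- max(abs(c(p_new - p, pn_new - pn)))
    p <- p_new; pn <- pn_new
    # parameter-change stop handles the geometric decay of pn toward 0
    if (abs(ll - ll_old) < tol || delta_par < 1e-8 || iter >= max_iter)
      break
    ll_old <- ll
  }
  list(r0 = pn, p_visible = p, iter = iter, loglik = ll,
       converged = iter < max_iter)
}

#' EM estimation of null-allele frequencies
#'
#' Per population and locus, estimates the frequency of a non-amplifying
#' (null) allele under Hardy-Weinberg proportions by
#' expectation-maximization over the latent true genotypes: apparent
#' homozygotes may be visible/null heterozygotes and missing genotypes are
#' treated as null homozygotes.
#'
#' @param ds a [genotype_dataset()]
#' @param min_n warn for cells with fewer than this many genotyped
#'   individuals (default 10).
#' @return `data.frame`: population, locus, `r0`, EM iterations,
#'   log-likelihood, convergence flag.
#' @export
null_allele_em <- function(ds, min_n = 10L) {
  prep <- pg_prep(ds)
  pop <- as.integer(ds$ind$pop)
  r <- nlevels(ds$ind$pop)
  out <- list()
  warned <- FALSE
  for (l in seq_along(prep)) {
    p <- prep[[l]]
    for (i in seq_len(r)) {
      sel <- pop == i
      a1 <- p$a1[sel]; a2 <- p$a2[sel]
      ok <- !is.na(a1)
      n_miss <- sum(!ok)
      if (sum(ok) < min_n && !warned) {
        warning("null-allele EM on cells with < ", min_n,
                " genotyped individuals")
        warned <- TRUE
      }
      K <- max(p$K, 1L)
      hom <- tabulate(a1[ok & a1 == a2], K)
      hetsel <- ok & a1 != a2
      hets <- tabulate(a1[hetsel], K) + tabulate(a2[hetsel], K)
      fit <- null_em_cell(hom, hets, n_miss)
      out[[length(out) + 1L]] <- data.frame(
        population = populations(ds)[i], locus = ds$loci[l], r0 = fit$r0,
        iter = fit$iter, loglik = fit$loglik, converged = fit$converged)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Theta recomputed with null-adjusted allele frequencies
#'
#' Replaces each population-by-locus visible allele frequency vector with
#' the EM-adjusted visible frequencies (renormalized after removing the
#' estimated null share) and recomputes the Weir-Cockerham components;
#' observed heterozygote counts are kept.  With a null frequency of zero
#' this reduces to the ordinary estimator.
#'
#' @param ds a [genotype_dataset()]
#' @param estimates result of [null_allele_em()].
#' @return a `theta_result` (no permutation test).
#' @export
fst_excluding_null <- function(ds, estimates) {
  prep <- pg_prep(ds)
  pop <- as.integer(ds$ind$pop)
  r <- nlevels(ds$ind$pop)
  comp <- matrix(0, length(prep), 3)
  for (l in seq_along(prep)) {
    p <- prep[[l]]
    ok <- !is.na(p$a1)
    if (!any(ok) || p$K < 2L) next
    ni <- tabulate(pop[ok], r)
    use <- which(ni > 0)
    if (length(use) < 2L) next
    # adjusted frequencies per pop
    piu <- matrix(0, length(use), p$K)
    hcnt <- matrix(0, length(use), p$K)
    for (k in seq_along(use)) {
      i <- use[k]
      sel <- ok & pop == i
      a1 <- p$a1[sel]; a2 <- p$a2[sel]
      hom <- tabulate(a1[a1 == a2], p$K)
      hetsel <- a1 != a2
      hets <- tabulate(a1[hetsel], p$K) + tabulate(a2[hetsel], p$K)
      est <- estimates[estimates$population == populations(ds)[i] &
                         estimates$locus == ds$loci[l], ]
      fit <- null_em_cell(hom, hets, n_miss = 0)
      q <- if (nrow(est) && !is.na(est$r0[1]) && est$r0[1] > 1e-8)
        fit$p_visible / sum(fit$p_visible)
      else (2 * hom + hets) / sum(2 * hom + hets)
      piu[k, ] <- q
      hcnt[k, ] <- hets
    }
    ni <- ni[use]; rr <- length(use)
    ntot <- sum(ni); nbar <- ntot / rr
    if (nbar <= 1) next
    nc <- (ntot - sum(ni^2) / ntot) / (rr - 1)
    pbar <- colSums(ni * piu) / ntot
    dev <- piu - matrix(pbar, rr, p$K, byrow = TRUE)
    s2 <- colSums(ni * dev^2) / ((rr - 1) * nbar)
    hbar <- colSums(hcnt) / ntot
    inner <- pbar * (1 - pbar) - (rr - 1) / rr * s2
    a_u <- nbar / nc * (s2 - (inner - hbar / 4) / (nbar - 1))
    b_u <- nbar / (nbar - 1) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
    c_u <- hbar / 2
    comp[l, ] <- c(sum(a_u), sum(b_u), sum(c_u))
  }
  theta <- theta_from_comp(comp)
  per_locus <- ifelse(rowSums(comp) == 0, NA_real_,
                      comp[, 1] / rowSums(comp))
  structure(list(theta = theta, per_locus = per_locus, se = NA_real_,
                 ci = c(NA_real_, NA_real_), p = NA_real_, n_perm = 0L),
            class = "theta_result")
}

## ---- genetic distances --------------------------------------------------

#' Nei (1972) standard genetic distance between all population pairs
#'
#' `D = -ln(J_xy / sqrt(J_x J_y))` with gene identities `J` averaged over
#' shared typed loci.  A zero between-population identity gives `Inf`
#' (flagged via the `infinite` attribute).
#'
#' @param ds a [genotype_dataset()]
#' @return a symmetric distance matrix (class `dist_matrix`, kind
#'   `genetic`).
#' @export
nei_distance <- function(ds) {
  af <- allele_frequencies(ds)
  pops <- populations(ds)
  r <- length(pops)
  D <- matrix(0, r, r, dimnames = list(pops, pops))
  for (i in seq_len(r - 1)) for (j in (i + 1):r) {
    jx <- jy <- jxy <- c()
    for (l in seq_along(af$freq)) {
      if (af$empty[i, l] || af$empty[j, l]) next
      fx <- af$freq[[l]][i, ]; fy <- af$freq[[l]][j, ]
      jx <- c(jx, sum(fx^2)); jy <- c(jy, sum(fy^2))
      jxy <- c(jxy, sum(fx * fy))
    }
    if (!length(jx)) { D[i, j] <- D[j, i] <- NA_real_; next }
    num <- mean(jxy)
    D[i, j] <- D[j, i] <- if (num <= 0) Inf else
      -log(num / sqrt(mean(jx) * mean(jy)))
  }
  structure(D, class = c("dist_matrix", "matrix"), kind = "genetic",
            infinite = any(is.infinite(D)))
}

#' Cavalli-Sforza & Edwards chord distance between population pairs
#'
#' Per locus `d_l = (2 sqrt(2) / pi) sqrt(1 - sum_u sqrt(p_xu p_yu))`,
#' averaged over shared typed loci.
#'
#' @param ds a [genotype_dataset()]
#' @return a symmetric distance matrix (class `dist_matrix`).
#' @export
cse_chord <- function(ds) {
  af <- allele_frequencies(ds)
  pops <- populations(ds)
  r <- length(pops)
  D <- matrix(0, r, r, dimnames = list(pops, pops))
  for (i in seq_len(r - 1)) for (j in (i + 1):r) {
    dl <- c()
    for (l in seq_along(af$freq)) {
      if (af$empty[i, l] || af$empty[j, l]) next
      cosb <- sum(sqrt(af$freq[[l]][i, ] * af$freq[[l]][j, ]))
      dl <- c(dl, (2 * sqrt(2) / pi) * sqrt(max(0, 1 - cosb)))
    }
    D[i, j] <- D[j, i] <- if (length(dl)) mean(dl) else NA_real_
  }
  structure(D, class = c("dist_matrix", "matrix"), kind = "genetic")
}

#' Write a distance matrix in PHYLIP square format
#'
#' First line the number of items, then one row per item: a name padded
#' to 10 characters followed by the distances.
#'
#' @param m symmetric matrix with row names.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_phylip <- function(m, file) {
  m <- as.matrix(m)
  nm <- rownames(m)
  if (is.null(nm)) nm <- paste0("item", seq_len(nrow(m)))
  lines <- c(sprintf("%5d", nrow(m)),
             vapply(seq_len(nrow(m)), function(i)
               paste0(formatC(substr(nm[i], 1, 10), width = -10),
                      paste(sprintf("%.6f", m[i, ]), collapse = "  ")),
               character(1)))
  writeLines(lines, file)
  invisible(file)
}

#' Rousset linearization of an F_ST matrix
#'
#' Elementwise `x / (1 - x)`, diagonal forced to 0; the standard transform
#' for isolation-by-distance regression on log distance.
#'
#' @param m F_ST matrix.
#' @return transformed matrix.
#' @export
linearized_fst <- function(m) {
  out <- m / (1 - m)
  diag(out) <- 0
  out
}
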