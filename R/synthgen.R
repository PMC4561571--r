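#' Island-model simulation specification
#'
#' Parameters for [simulate_island_genotypes()]: a finite island model of
#' `n_pops` demes of `N` diploids exchanging migrants at rate `m` per
#' lineage per generation, genotyped at `n_loci` unlinked SSR loci mutating
#' under the stepwise mutation model at rate `mu` per locus per generation.
#'
#' @param n_pops number of demes.
#' @param n_ind diploid individuals sampled per deme.
#' @param n_loci number of SSR loci.
#' @param N deme size (diploids), `>= 2`.
#' @param m per-generation migration rate per lineage, in `[0, 1]`.
#' @param mu stepwise mutation rate per locus per generation, `> 0` unless
#'   `m > 0`.
#' @param root_sizes ancestral repeat count(s); a vector is recycled over
#'   demes and matters only for demes that never share ancestry (`m = 0`).
#' @return a list of class `island_model_spec`.
#' @export
island_model_spec <- function(n_pops, n_ind, n_loci, N, m, mu,
                              root_sizes = 100L) {
  stopifnot(n_pops >= 1, n_ind >= 1, n_loci >= 1)
  if (N < 2) stop("deme size N must be >= 2")
  if (m < 0 || m > 1) stop("migration rate m must be in [0, 1]")
  if (mu < 0) stop("mutation rate mu must be nonnegative")
  if (m == 0 && mu == 0 && n_pops > 1 && length(unique(root_sizes)) == 1L)
    stop("non-convergent settings: m = 0 with mu = 0 gives no variation")
  structure(list(n_pops = as.integer(n_pops), n_ind = as.integer(n_ind),
                 n_loci = as.integer(n_loci), N = N, m = m, mu = mu,
                 root_sizes = as.integer(root_sizes)),
            class = "island_model_spec")
}

# allele-size bounds shared by all SSR simulators: keeps 3-digit Genepop
# coding valid with reflecting boundaries
SSR_SIZE_MIN <- 50L
SSR_SIZE_MAX <- 300L

#' Simulate SSR genotypes under a finite island model
#'
#' Runs a structured coalescent at stationarity (backward in time, with
#' symmetric island migration) and drops stepwise mutations on the
#' genealogy, giving an equilibrium sample whose expected multilocus
#' differentiation follows the finite-island prediction
#' `theta ~ 1 / (1 + 4Nm (d/(d-1))^2)` for `d` demes when mutation is weak.
#'
#' @param spec an [island_model_spec()].
#' @param seed integer seed; the simulation is bit-reproducible under it.
#' @return a [genotype_dataset()] with populations `pop01`, `pop02`, ...;
#'   attribute `tmrca` carries the per-locus tree heights (generations).
#' @export
simulate_island_genotypes <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "island_model_spec"))
  set.seed(seed)
  P <- spec$n_pops
  mig <- matrix(if (P > 1) spec$m / (P - 1) else 0, P, P)
  diag(mig) <- 0
  geno <- cpp_coal_migration(rep(spec$n_ind, P), spec$N, mig, spec$mu,
                             spec$n_loci,
                             rep_len(spec$root_sizes, P),
                             SSR_SIZE_MIN, SSR_SIZE_MAX)
  pops <- sprintf("pop%02d", rep(seq_len(P), each = spec$n_ind))
  ds <- genotype_dataset(geno, pop = factor(pops, levels = unique(pops)))
  attr(ds, "tmrca") <- attr(geno, "tmrca")
  ds
}

#' Simulate SSR genotypes under a one-dimensional stepping-stone model
#'
#' Demes sit on a line; each exchanges migrants only with its immediate
#' neighbours (rate `m/2` to each side, `m` at the ends), so pairwise
#' differentiation increases with inter-deme distance in expectation —
#' the fixture for isolation-by-distance analyses.
#'
#' @param n_pops number of demes (`>= 4`).
#' @param N deme size (diploids).
#' @param m total migration rate per lineage per generation; `m = 0` warns
#'   (no isolation-by-distance signal possible).
#' @param mu stepwise mutation rate per locus per generation.
#' @param n_ind diploids sampled per deme.
#' @param n_loci number of loci.
#' @param spacing_km inter-deme distance along the line (km).
#' @param seed integer seed.
#' @return a [genotype_dataset()] with metadata placing demes every
#'   `spacing_km` km along a parallel of latitude 35 N.
#' @export
simulate_stepping_stone <- function(n_pops, N, m, mu, n_ind, n_loci,
                                    spacing_km = 20, seed = 1L) {
  if (n_pops < 4) stop("stepping-stone model needs >= 4 demes")
  if (m == 0) warning("m = 0: no isolation-by-distance signal")
  set.seed(seed)
  mig <- matrix(0, n_pops, n_pops)
  for (i in seq_len(n_pops)) {
    nb <- c(i - 1L, i + 1L)
    nb <- nb[nb >= 1L & nb <= n_pops]
    mig[i, nb] <- m / length(nb)
  }
  geno <- cpp_coal_migration(rep(as.integer(n_ind), n_pops), N, mig, mu,
                             as.integer(n_loci), 100L,
                             SSR_SIZE_MIN, SSR_SIZE_MAX)
  pops <- sprintf("pop%02d", rep(seq_len(n_pops), each = n_ind))
  ds <- genotype_dataset(geno, pop = factor(pops, levels = unique(pops)))
  # place demes on a line of constant latitude; 1 degree lon ~ 91.29 km at 35N
  km_per_deg <- pi * 6371 / 180 * cos(35 * pi / 180)
  meta <- data.frame(population = unique(pops), state = "NC",
                     lat = 35, lon = -80 + (seq_len(n_pops) - 1) *
                       spacing_km / km_per_deg)
  attach_metadata(ds, meta)
}

#' Dose-response simulation specification
#'
#' Parameters for [simulate_dose_response()], emulating a two-replicate
#' greenhouse screen: each plant's survival is Bernoulli with probability
#' given by the four-parameter Weibull curve at its dose (population's own
#' ED50), with an additive log-odds shift for the second replicate
#' greenhouse (the replicate acts as a nuisance on survival, not on ED50).
#'
#' @param ed50 named vector of true per-population ED50 values (kg a.i./ha,
#'   `> 0`); names are population IDs.
#' @param doses dose ladder in kg a.i./ha (default the 6-dose design
#'   0, 0.21, 0.42, 0.84, 1.70, 3.40).
#' @param b shared Weibull slope (`> 0`).
#' @param c_upper,d_lower upper/lower survival asymptotes,
#'   `0 <= d_lower < c_upper <= 1`.
#' @param n_per_dose plants per population per dose per replicate.
#' @param replicate_shift additive shift on log-odds survival applied to
#'   replicate 2.
#' @return a list of class `dose_sim_spec`.
#' @export
dose_sim_spec <- function(ed50, doses = c(0, 0.21, 0.42, 0.84, 1.70, 3.40),
                          b = 2, c_upper = 1, d_lower = 0, n_per_dose = 10,
                          replicate_shift = 0) {
  if (any(ed50 <= 0)) stop("ED50 values must be positive")
  if (b <= 0) stop("slope b must be positive")
  if (!(d_lower >= 0 && d_lower < c_upper && c_upper <= 1))
    stop("need 0 <= d_lower < c_upper <= 1")
  if (is.null(names(ed50)))
    names(ed50) <- sprintf("pop%02d", seq_along(ed50))
  structure(list(ed50 = ed50, doses = doses, b = b, c_upper = c_upper,
                 d_lower = d_lower, n_per_dose = as.integer(n_per_dose),
                 replicate_shift = replicate_shift),
            class = "dose_sim_spec")
}

# Weibull survival curve Y(x) = d + (c-d) exp(-exp(b (ln x - ln e))),
# with Y(0) = c as the x -> 0 limit; `e` is the dose-scale parameter and
# the absolute ED50 is e (ln 2)^(1/b).
weibull_curve <- function(x, c_upper, d_lower, b, e) {
  y <- ifelse(x <= 0, c_upper,
              d_lower + (c_upper - d_lower) * exp(-exp(b * (log(pmax(x, 1e-300)) - log(e)))))
  y
}

# dose-scale parameter e giving ED50_abs = target under slope b
e_from_ed50 <- function(ed50_abs, b) ed50_abs / log(2)^(1 / b)

#' Simulate a two-replicate greenhouse dose-response experiment
#'
#' @param spec a [dose_sim_spec()].
#' @param seed integer seed.
#' @return a phenotype `data.frame` (columns `individual`, `population`,
#'   `replicate`, `dose`, `survival`) in the layout of
#'   [read_phenotypes()].
#' @export
simulate_dose_response <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "dose_sim_spec"))
  set.seed(seed)
  grid <- expand.grid(population = names(spec$ed50), dose = spec$doses,
                      replicate = 1:2, plant = seq_len(spec$n_per_dose),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  e <- e_from_ed50(spec$ed50[grid$population], spec$b)
  p <- weibull_curve(grid$dose, spec$c_upper, spec$d_lower, spec$b, e)
  shift <- ifelse(grid$replicate == 2L, spec$replicate_shift, 0)
  p <- stats::plogis(stats::qlogis(pmin(pmax(p, 0), 1)) + shift)
  p[is.nan(p)] <- 0 # qlogis(0) + shift stays 0; guard the -Inf + Inf corner
  out <- data.frame(
    individual = sprintf("%s_r%d_d%g_%02d", grid$population, grid$replicate,
                         grid$dose, grid$plant),
    population = grid$population,
    replicate = as.integer(grid$replicate),
    dose = grid$dose,
    survival = as.integer(stats::runif(nrow(grid)) < p),
    stringsAsFactors = FALSE
  )
  out[order(out$population, out$replicate, out$dose), , drop = FALSE]
}

#' Overlay null alleles on a genotype dataset
#'
#' Each allele copy independently fails to amplify with probability `r0`
#' for its locus.  A genotype with both copies null becomes missing; a
#' genotype with one null copy appears as a homozygote for the visible
#' allele — the classic cause of apparent heterozygote deficit.
#'
#' @param ds a [genotype_dataset()].
#' @param r0 per-locus null-allele frequency, recycled over loci, each in
#'   `[0, 1)`.
#' @param seed integer seed.
#' @return the modified dataset.
#' @export
inject_null_alleles <- function(ds, r0, seed = 1L) {
  stopifnot(inherits(ds, "genotype_dataset"))
  r0 <- rep_len(r0, length(ds$loci))
  if (any(r0 < 0 | r0 >= 1)) stop("null frequency r0 must be in [0, 1)")
  set.seed(seed)
  al <- ds$alleles
  for (l in seq_along(ds$loci)) {
    if (r0[l] == 0) next
    cols <- c(2L * l - 1L, 2L * l)
    a <- al[, cols, drop = FALSE]
    isnull <- matrix(stats::runif(length(a)) < r0[l], ncol = 2L) & !is.na(a)
    both <- isnull[, 1] & isnull[, 2]
    a[both, ] <- NA_integer_
    one1 <- isnull[, 1] & !isnull[, 2]
    one2 <- isnull[, 2] & !isnull[, 1]
    a[one1, 1] <- a[one1, 2]
    a[one2, 2] <- a[one2, 1]
    al[, cols] <- a
  }
  ds$alleles <- al
  ds
}

#' Study-shaped synthetic preset
#'
#' A full synthetic landscape mirroring the sampling design the analyses
#' assume: 44 populations in 6 states across 2 regions (IN, OH Midwestern;
#' VA, NC, SC, TN Southeastern), about 18 genotyped individuals per
#' population at 15 SSR loci, and a 2-replicate greenhouse dose-response
#' design with the 6-dose ladder (0, 0.21, 0.42, 0.84, 1.70, 3.40 kg
#' a.i./ha) and 10 plants per population and treatment.  Twelve
#' Southeastern populations carry a high true ED50 (resistant hotspots),
#' nineteen a low one, the remainder sit at the species-typical 1.6 kg
#' a.i./ha, so the landscape is a resistance mosaic.
#'
#' @param seed integer seed.
#' @param n_ind genotyped individuals per population.
#' @param n_loci SSR loci.
#' @param fst_target approximate equilibrium differentiation used to pick
#'   the island-model migration rate.
#' @return list with elements `genotypes` ([genotype_dataset()] with
#'   metadata), `phenotypes` (phenotype table), `metadata`, and
#'   `true_ed50`.
#' @export
study_preset <- function(seed = 1L, n_ind = 18, n_loci = 15,
                         fst_target = 0.12) {
  state_counts <- c(IN = 7, OH = 8, VA = 6, NC = 9, SC = 7, TN = 7)
  states <- rep(names(state_counts), state_counts)
  n_pops <- length(states) # 44
  pop_ids <- sprintf("%s%02d", states, stats::ave(seq_len(n_pops), states,
                                                  FUN = seq_along))
  state_centre <- list(IN = c(39.8, -86.3), OH = c(40.2, -83.0),
                       VA = c(37.4, -78.7), NC = c(35.5, -79.2),
                       SC = c(34.0, -81.0), TN = c(35.8, -86.4))
  set.seed(seed)
  cc <- do.call(rbind, state_centre[states])
  meta <- data.frame(population = pop_ids, state = states,
                     lat = cc[, 1] + stats::runif(n_pops, -0.8, 0.8),
                     lon = cc[, 2] + stats::runif(n_pops, -1.0, 1.0))
  # island model tuned so theta ~ fst_target: 4Nm = (1/t - 1)/(d/(d-1))^2
  d <- n_pops
  four_nm <- (1 / fst_target - 1) / (d / (d - 1))^2
  N <- 500
  spec <- island_model_spec(n_pops, n_ind, n_loci, N = N,
                            m = four_nm / (4 * N), mu = 5e-4)
  geno <- simulate_island_genotypes(spec, seed = seed + 1L)
  levels(geno$ind$pop) <- pop_ids
  geno <- attach_metadata(geno, meta)
  # resistance mosaic: 12 resistant SE pops; 19 susceptible (7 MW + 12 SE),
  # rest at the species-typical ED50 -- hotspots neighbour susceptible pops
  by_state <- split(seq_len(n_pops), states)
  resistant <- c(by_state$VA[1:3], by_state$NC[1:3],
                 by_state$SC[1:3], by_state$TN[1:3])
  susceptible <- c(by_state$IN[1:4], by_state$OH[1:3],
                   by_state$NC[4:8], by_state$SC[4:7], by_state$TN[4:6])
  ed50 <- rep(1.6, n_pops)
  ed50[resistant] <- 4.5
  ed50[susceptible] <- 0.7
  names(ed50) <- pop_ids
  dspec <- dose_sim_spec(ed50, b = 2, c_upper = 0.98, d_lower = 0,
                         n_per_dose = 10, replicate_shift = -0.2)
  pheno <- simulate_dose_response(dspec, seed = seed + 2L)
  pheno <- attach_metadata(pheno, meta)
  list(genotypes = geno, phenotypes = pheno, metadata = meta,
       true_ed50 = ed50)
}
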