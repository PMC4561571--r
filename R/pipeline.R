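## End-to-end driver: synthetic study -> resistance classification,
## differentiation report, spatial report, ABC posterior table.

#' Subset a genotype dataset to selected populations
#'
#' @param ds a [genotype_dataset()]
#' @param pops population IDs to keep (order preserved as given).
#' @param rename optional new labels for the kept populations.
#' @return a [genotype_dataset()]
#' @export
subset_populations <- function(ds, pops, rename = NULL) {
  missing_p <- setdiff(pops, populations(ds))
  if (length(missing_p))
    stop("unknown populations: ", paste(missing_p, collapse = ", "))
  sel <- which(ds$ind$pop %in% pops)
  sel <- sel[order(match(ds$ind$pop[sel], pops))]
  newpop <- factor(as.character(ds$ind$pop[sel]), levels = pops)
  if (!is.null(rename)) levels(newpop) <- rename
  meta <- NULL
  if (!is.null(ds$meta) && is.null(rename)) {
    meta <- ds$meta[match(pops, ds$meta$population), ]
    rownames(meta) <- NULL
  }
  genotype_dataset(ds$alleles[sel, , drop = FALSE], pop = newpop,
                   id = ds$ind$id[sel], loci = ds$loci, meta = meta)
}

#' Four-trial ABC driver over population quartets
#'
#' Mirrors the trial protocol: each trial takes two populations from each
#' of two focal states, computes the observed summary vector for the
#' quartet, and runs model choice against a shared reference table; the
#' last row averages the posteriors across trials.
#'
#' @param ds genotyped dataset with metadata attached.
#' @param ref an `abc_reference` built for the generic 2+2 design.
#' @param scenarios list from [build_scenarios()].
#' @param states two state codes to draw quartets from (default NC, TN).
#' @param n_trials number of trials (default 4).
#' @param tolerance retained fraction per model choice.
#' @param seed integer seed for quartet sampling.
#' @return `data.frame`: trial, populations, posterior and CI per
#'   scenario.
#' @export
abc_trials <- function(ds, ref, scenarios, states = c("NC", "TN"),
                       n_trials = 4L, tolerance = 0.01, seed = 1L) {
  if (is.null(ds$meta)) stop("metadata required to pick state populations")
  set.seed(seed)
  g1 <- ds$meta$population[ds$meta$state == states[1]]
  g2 <- ds$meta$population[ds$meta$state == states[2]]
  if (length(g1) < 2L || length(g2) < 2L)
    stop("need >= 2 populations in each focal state")
  rows <- list()
  post_mat <- ci_lo <- ci_hi <- NULL
  for (tr in seq_len(n_trials)) {
    quartet <- c(sample(g1, 2L), sample(g2, 2L))
    sub <- subset_populations(ds, quartet, rename = scenarios[[1]]$pops)
    res <- abc_model_choice(ref, summary_stats(sub), tolerance)
    post_mat <- rbind(post_mat, res$logistic)
    ci_lo <- rbind(ci_lo, res$ci["lower", ])
    ci_hi <- rbind(ci_hi, res$ci["upper", ])
    rows[[tr]] <- data.frame(trial = tr,
                             populations = paste(quartet, collapse = ","))
  }
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(trial = NA, populations = "average"))
  post_mat <- rbind(post_mat, colMeans(post_mat))
  ci_lo <- rbind(ci_lo, colMeans(ci_lo))
  ci_hi <- rbind(ci_hi, colMeans(ci_hi))
  for (k in seq_len(ncol(post_mat))) {
    nm <- colnames(post_mat)[k]
    out[[paste0(nm, "_posterior")]] <- post_mat[, k]
    out[[paste0(nm, "_lower")]] <- ci_lo[, k]
    out[[paste0(nm, "_upper")]] <- ci_hi[, k]
  }
  out
}

#' Run the full synthetic-study pipeline
#'
#' Generates the study-shaped synthetic landscape and runs every stage:
#' dose-response ED50 estimation with bootstrap species CI and population
#' classification; differentiation statistics (theta, R_ST, AMOVA,
#' pairwise F_ST, Nei distance + PCoA); spatial analyses (Moran
#' correlogram, isolation-by-distance Mantel tests, delta-resistance
#' PCoA); and the four-trial ABC model choice.  All outputs are written
#' as delimited text files under `outdir`; the run is deterministic under
#' `seed`.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer seed.
#' @param n_perm permutations for the significance tests.
#' @param n_ref ABC reference-table simulations per scenario.
#' @param bootstrap_B bootstrap replicates for the species CI.
#' @param classify_dose dose (kg a.i./ha) at which populations are
#'   classified against the species CI.
#' @return invisible list of the main result objects.
#' @export
pipeline_run <- function(outdir, seed = 1L, n_perm = 199L, n_ref = 2000L,
                         bootstrap_B = 1000L, classify_dose = 1.7) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  preset <- study_preset(seed = seed)
  geno <- preset$genotypes
  pheno <- preset$phenotypes
  write_genepop(geno, file.path(outdir, "genotypes.gen"),
                title = "synthetic study preset")
  utils::write.csv(pheno, file.path(outdir, "phenotypes.csv"),
                   row.names = FALSE)
  utils::write.csv(preset$metadata, file.path(outdir, "metadata.csv"),
                   row.names = FALSE)

  ## dose-response stage
  fits <- rbind(ed50_table(pheno, by = "species"),
                ed50_table(pheno, by = "region"),
                ed50_table(pheno, by = "state"))
  utils::write.csv(fits, file.path(outdir, "ed50_fits.csv"),
                   row.names = FALSE)
  at_dose <- pheno[pheno$dose == classify_dose, ]
  pop_means <- tapply(at_dose$survival, at_dose$population, mean)
  ci <- bootstrap_species_ci(as.numeric(pop_means), B = bootstrap_B,
                             seed = seed, dose = classify_dose)
  cls <- classify_populations(stats::setNames(as.numeric(pop_means),
                                              names(pop_means)), ci)
  utils::write.csv(cls, file.path(outdir, "resistance_classification.csv"),
                   row.names = FALSE)

  ## differentiation stage
  th <- wc_theta(geno, n_perm = n_perm, seed = seed)
  rs <- rst(geno)
  am <- amova(geno, n_perm = n_perm, seed = seed)
  pw <- pairwise_fst_matrix(geno, n_perm = 0L)
  nd <- nei_distance(geno)
  pc_gen <- pcoa(nd, n_axes = 2L)
  diff_report <- data.frame(
    statistic = c("theta", "theta_ci_lo", "theta_ci_hi", "theta_p",
                  "rst", "rst_ci_lo", "rst_ci_hi",
                  "F_RT", "F_SR", "F_PS", "F_IT",
                  "F_RT_p", "F_SR_p", "F_PS_p", "F_IT_p"),
    value = c(th$theta, th$ci, th$p, rs$rst, rs$ci,
              am$F, am$p))
  utils::write.csv(diff_report, file.path(outdir, "differentiation.csv"),
                   row.names = FALSE)
  utils::write.table(round(pw$fst, 6),
                     file.path(outdir, "pairwise_fst.tsv"), sep = "\t",
                     quote = FALSE)
  utils::write.csv(data.frame(population = rownames(pc_gen$coords),
                              axis1 = pc_gen$coords[, 1],
                              axis2 = pc_gen$coords[, 2]),
                   file.path(outdir, "pcoa_genetic.csv"),
                   row.names = FALSE)

  ## spatial stage
  geo <- haversine_km(preset$metadata)
  ord <- match(names(pop_means), preset$metadata$population)
  geo_o <- structure(unclass(geo)[ord, ord],
                     class = c("dist_matrix", "matrix"),
                     kind = "geographic_km")
  correlog <- moran_correlogram(as.numeric(pop_means), geo_o,
                                n_perm = n_perm, seed = seed)
  utils::write.csv(correlog, file.path(outdir, "moran_correlogram.csv"),
                   row.names = FALSE)
  ord2 <- match(populations(geno), preset$metadata$population)
  geo_g <- structure(unclass(geo)[ord2, ord2],
                     class = c("dist_matrix", "matrix"),
                     kind = "geographic_km")
  ibd <- mantel_ibd(pw$fst, geo_g, "linearized_fst_vs_ln_km",
                    n_perm = n_perm, seed = seed)
  ibd_chord <- mantel_ibd(cse_chord(geno), geo_g, "chord_vs_ln_km",
                          n_perm = n_perm, seed = seed)
  utils::write.csv(data.frame(
    test = c("linearized_fst_vs_ln_km", "chord_vs_ln_km"),
    slope = c(ibd$slope, ibd_chord$slope),
    r = c(ibd$r, ibd_chord$r),
    p = c(ibd$p, ibd_chord$p)),
    file.path(outdir, "ibd_mantel.csv"), row.names = FALSE)
  dres <- delta_resistance(stats::setNames(as.numeric(pop_means),
                                           names(pop_means)))
  pc_res <- pcoa(dres, n_axes = 2L)
  utils::write.csv(data.frame(population = names(pop_means),
                              axis1 = pc_res$coords[, 1],
                              axis2 = pc_res$coords[, 2]),
                   file.path(outdir, "pcoa_resistance.csv"),
                   row.names = FALSE)

  ## ABC stage
  scenarios <- build_scenarios()
  priors <- prior_spec()
  ref <- suppressWarnings(
    build_reference_table(scenarios, priors, n_per_scenario = n_ref,
                          seed = seed, n_ind = 18L, n_loci = 15L))
  write_reference_table(ref, file.path(outdir, "abc_reference.tsv"))
  trials <- abc_trials(geno, ref, scenarios, states = c("NC", "TN"),
                       n_trials = 4L, seed = seed)
  utils::write.csv(trials, file.path(outdir, "abc_posteriors.csv"),
                   row.names = FALSE)

  invisible(list(fits = fits, species_ci = ci, classification = cls,
                 theta = th, rst = rs, amova = am, pairwise = pw,
                 correlogram = correlog, ibd = ibd, trials = trials))
}
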