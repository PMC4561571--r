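---
title: "Methods: dose-response, population structure and admixture-scenario choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response, population structure and admixture-scenario choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resmosaic)
```

# The scientific question

When herbicide resistance appears in many populations of a weed across a
landscape, two histories can explain it: resistance alleles spread between
farms by gene flow, or each population evolved resistance on its own under
local selection.  The two histories make different predictions.  Spread by
gene flow predicts isolation by distance in the resistance phenotype and in
neutral markers, and recent admixture between resistant populations.
Independent origin predicts a *resistance mosaic* — highly resistant
populations neighbouring susceptible ones — with no isolation by distance,
and any admixture predating the onset of herbicide use.

`resmosaic` implements the full analysis chain needed to distinguish these
histories for a mixed-mating annual weed sampled as: 44 populations from 6
states in 2 US regions (Midwest: IN, OH; Southeast: VA, NC, SC, TN), a
replicated greenhouse dose-response screen (2 greenhouse replicates, 6
glyphosate doses: 0, 0.21, 0.42, 0.84, 1.70, 3.40 kg a.i./ha, ~10 plants
per population and treatment), and ~18 individuals per population genotyped
at 15 unlinked SSR loci.  Because no field data are distributed with the
package, a synthetic-data module generates datasets with the statistical
structure the analyses assume; every claim the test suite makes is about
estimator behaviour on data of that structure, not about any real
population.

# Dose-response model

Survival is modelled by the four-parameter Weibull curve

$$Y(x) = d + (c - d)\,\exp\!\big(-\exp\big(b(\ln x - \ln e)\big)\big),$$

with upper asymptote $c = Y(0)$ (survival of water controls), lower
asymptote $d = Y(\infty)$, slope $b > 0$ and dose-scale parameter $e$.
Dose 0 is handled as the $x \to 0$ limit ($Y(0) \equiv c$), which keeps the
likelihood continuous without taking $\ln 0$.  The curve crosses the
midpoint of its asymptotes at

$$\mathrm{ED}_{50} = e\,(\ln 2)^{1/b},$$

which is what the package reports everywhere.  $e$ itself solves
$Y(e) = d + (c-d)/\mathrm e$, i.e. the 37% point between the asymptotes;
equating $e$ with the ED50 is exact only as $b \to \infty$, so both numbers
are returned and the absolute ED50 is used for all downstream comparisons.

Fitting minimises the binomial negative log-likelihood for raw 0/1
survival, or (weighted) least squares for replicate-adjusted responses.
The data enter only through per-dose sufficient statistics, so fits on
thousands of plants cost the same as fits on six dose means.  Optimisation
is multi-start Nelder-Mead + BFGS from five deterministic initialisations
whose dose-scale starting points span the positive dose range; ties are
broken by objective value and then by smaller $b$, making the fit
reproducible.  The covariance of $(\ln e, b)$ comes from the inverse
curvature at the optimum and feeds a delta-method CI for
$\ln \mathrm{ED}_{50}$.

## Replicate adjustment

The two greenhouse replicates differ in overall mortality.  Following
standard practice for dose-response screens, survival is regressed on the
replicate indicator by logistic regression and the response-scale
residuals, re-centred by the grand mean, replace the raw values; this
preserves the overall mean exactly and removes the between-replicate gap
in expectation.  A replicate with all-identical outcomes separates the
logistic fit, in which case raw values are returned with a warning.

One limitation is worth stating plainly: the synthetic generator applies
the replicate effect as an additive shift on the log-odds of survival,
which vanishes where survival is 0 or 1.  A constant response-scale
correction therefore cannot undo it exactly at intermediate doses, and a
very strong shift biases the pooled ED50 downward.  The default shift in
the study-shaped preset is $-0.2$ log-odds, calibrated to the magnitude a
replicate effect of the reported strength implies (a chi-square of ~8 on
~4600 plants corresponds to a logistic coefficient near 0.17); at that
realistic magnitude the residual bias is well inside the 10% recovery
tolerance the tests use.

## Species CI and population classification

The species-level survival CI is a nonparametric bootstrap over
populations: population mean survivals are resampled with replacement
(default $B = 1000$) and the 2.5% and 97.5% percentiles of the resampled
mean-of-means form the interval.  Populations are classified `above`,
`within` or `below` the closed interval — the package's analogue of
flagging resistant and susceptible populations.

# Population-genetic statistics

All estimators use pairwise-complete data per locus: an individual missing
at a locus is dropped from that locus only.  Allele codes are sizes (or
repeat counts) in 1..999, the 3-digit Genepop convention.

* **Weir-Cockerham theta.** Variance components per allele and locus
  (among populations $a$, among individuals within populations $b$, within
  individuals $c$) with the 1984 unequal-sample-size corrections;
  $\hat\theta = \sum a / \sum (a+b+c)$ over alleles and loci.  The 95% CI
  is a delete-one-locus jackknife; significance permutes whole multilocus
  genotypes among populations.  The permutation unit is genotypes (not
  alleles): individuals are the exchangeable objects under the no-structure
  null when Hardy-Weinberg departures are possible within populations.
* **Pairwise F_ST** uses the same estimator per population pair, a
  permutation test per pair, and Holm step-down (the modern form of
  sequential Bonferroni) across all pairs.
* **R_ST** replaces allele identity with allele size: a two-level
  variance-component estimator on sizes, components summed over loci,
  jackknife CI over loci.  Permuting which size plays which allelic role
  changes R_ST but not theta — the definitional contrast between the two.
* **Hierarchical AMOVA** partitions allele-identity variance over
  region / state-within-region / population-within-state /
  individual / within-individual.  Components are method-of-moments
  solutions of the expected-SS linear system, computed exactly for
  unequal sample sizes from nested group sizes (the textbook balanced
  coefficients fall out as a special case, which the tests exploit as an
  oracle).  Negative components are truncated to zero only when forming
  the F ratios (F_RT, F_SR, F_PS, F_IT) and reported raw otherwise.  A
  level that does not refine its parent (a single region, or one
  population per state) is dropped and its F is `NA`.  Permutation tests
  move whole populations among regions, populations among states within
  regions, individuals among populations within states, and allele copies
  among individuals within populations.
* **HWE exact test** uses Levene's conditional distribution given allele
  counts (the probability test): full enumeration for up to 3 alleles and
  $n \le 50$, Monte-Carlo resampling of the conditional distribution
  otherwise.  Like any exact test on discrete data it is conservative for
  tiny samples; calibration checks therefore use $n = 50$ with 4 alleles,
  where the null distribution of the p-value is close to uniform.
* **Genotypic LD** uses the G statistic on the two-locus genotype table
  with permutation of single-locus genotypes among individuals, combined
  across populations by Fisher's method.
* **Null alleles** are estimated per population and locus by EM under
  Hardy-Weinberg with one unobservable allele: apparent homozygotes are
  mixtures of true homozygotes and visible/null heterozygotes, and missing
  genotypes are treated as null homozygotes.  The corrected theta
  recomputes the components from the EM-adjusted visible frequencies
  (renormalised after removing the null share) while keeping observed
  heterozygote counts; at a null frequency of zero it reduces to the
  ordinary estimator, which the tests assert.
* **Distances.** Nei (1972) standard distance with gene identities
  averaged over shared loci, and the Cavalli-Sforza-Edwards chord distance
  $(2\sqrt2/\pi)\sqrt{1 - \sum_u \sqrt{p_{xu} p_{yu}}}$ averaged over
  loci.  Isolation by distance regresses $F_{ST}/(1-F_{ST})$ (or chord
  distance) on log kilometres with a one-sided Mantel label-permutation
  test.

All permutation p-values are computed as $(1 + \#\{T^* \ge T\})/(1 + B)$,
which avoids zero p-values and keeps the tests exact.

# Spatial analyses

Great-circle distances use the haversine formula on a 6371.0 km sphere.
Moran's I correlograms use binary distance-class weights; the default
classes put the first break at 64.4 km (40 miles — the local scale of
interest in resistance mosaics) and split the remaining pairs into
deciles.  The permutation null mean of I is $-1/(n-1)$ and the two-sided
p-value counts permutations whose deviation from that mean reaches the
observed one.  PCoA is classical scaling (Gower double-centering of
$-D^2/2$); negative eigenvalues are reported as diagnostics and left
uncorrected, and axis proportions are taken over positive eigenvalues
only.

# Coalescent simulator and ABC model choice

The ABC stage asks: did admixture between the two most resistant regions
happen before or after herbicide use began, or not at all?  Three
scenarios share a topology over four sampled populations (two per
region): within-region splits at $t_w$, a regional divergence at $t_2$, a
species origin at $t_1$, and a 90% bottleneck at $t_3 = 39$ generations
before present (the 1974 commercial release of the herbicide for a 2013
sample of an annual).  Scenario 2 adds an admixture pulse at
$t_4 \in (t_3, t_2)$ from the merged ancestral lineage of the donor
region into one recipient population; scenario 3 places the pulse at
$t_5 \in \{2,\dots,38\}$, after herbicide use began.  Priors:
$N_e \sim U(250, 1000)$ with recent size $0.1\,N_e$,
$t_1 \sim U(180, 210)$, $t_2 \sim U(t_3+1, t_1)$, admixture proportion
$r \sim U(0.1, 0.9)$, and SSR mutation rate
$\mu \sim \mathrm{LogUniform}(10^{-4}, 10^{-3})$ per locus per generation
under the strict stepwise model (the original prior table is not
available; these are conventional SSR ABC defaults and should be treated
as such).  Ordering constraints are enforced by rejection-resampling.

The simulator is an event-driven backward coalescent (implemented in
C++): within a deme of $N$ diploids, $k$ lineages coalesce at rate
$k(k-1)/2$ per $2N$ generations; merges, size changes and admixture
events modify the deme structure at their times; mutations are Poisson on
branches, $\pm1$ repeat with reflecting bounds at 50 and 300 repeats so
allele sizes stay valid 3-digit codes.  The same engine, with a migration
matrix instead of events, generates the equilibrium island and
stepping-stone datasets used across the test suite; its two-lineage mean
time to coalescence and its equilibrium heterozygosity
$1 - 1/\sqrt{1 + 8N\mu}$ are checked against theory.

Summaries per simulated dataset: per population, mean alleles per locus,
expected heterozygosity, allele-size variance and M-ratio; per pair,
theta and the mean squared difference in mean allele size.  Model choice
standardises summaries by the reference table's means and SDs, retains
the closest 1% by Euclidean distance (the tolerance is a free parameter;
1% of 30,000 simulations gives 300 local points), and reports the
scenario frequencies among retained rows alongside a local multinomial
logistic estimate: the standardised summaries are first projected onto
the linear discriminant axes separating the scenarios (trained on the
whole table), and the Epanechnikov-weighted multinomial regression is
evaluated at the observed point on those axes.  Without the projection a
3-class logistic on ~30 summaries would fit ~60 parameters to 300 local
rows; on two discriminant axes it is well-conditioned.  CIs come from
the regression covariance pushed through the softmax.

Scenario identifiability is limited by the design, not by the estimator.
An old admixture pulse with small $r$, or one placed just before the
regional divergence, is statistically indistinguishable from no
admixture at 15 SSR loci, and a substantial share of scenario 2's prior
volume lies in that region: held-out classification on large reference
tables — whether by discriminant analysis or by gradient-boosted trees —
recovers scenario 2 only at rates barely above its confusion with
scenario 1, while recent admixture (scenario 3) is conspicuous.  Two
consequences for validation are worth stating.  First, plurality
recovery of scenario 2 over prior-drawn pseudo-observed datasets sits at
the edge of what the model permits, and a 50-dataset experiment can land
on either side of it.  Second, under these priors the presence of *old*
admixture is a harder call than admixture timing, so the intuition that
"timing is harder than presence" inverts.  A strongly supported
pre-herbicide-admixture posterior on observed data is therefore
informative exactly because such data must be atypical of the competing
scenarios, not because the scenarios are generically well separated.

# Synthetic study preset

`study_preset()` assembles the full landscape: 44 populations with
state-typical coordinates jittered within ~1 degree; an island-model
genotype dataset whose migration rate is chosen from the target
equilibrium differentiation (default $\theta \approx 0.12$, the
moderate-structure regime the analyses expect); and a dose-response
experiment in which 12 Southeastern populations carry a high true ED50
(4.5 kg a.i./ha), 19 populations a low one (0.7), and the rest the
species-typical 1.6 — a mosaic in which hotspots neighbour susceptible
populations.  What the preset deliberately does *not* emulate: genotyping
error and allele dropout, uneven germination, spatially autocorrelated
neutral structure (the island model is exchangeable), or linkage between
loci.  Tests passing on the preset therefore validate the estimators and
the pipeline plumbing, not robustness to those real-data pathologies.

Problem sizes used by the checks: the calibration study runs 500
panmictic datasets (4 populations of 8 at 5 loci) per test family with
99 permutations each; ED50 recovery uses 100 replicate studies at the
full design scale; the ABC self-consistency study uses 10,000 simulations
per scenario and 50 pseudo-observed datasets per scenario at 15 loci and
18 diploids per population; the end-to-end run uses 1,000-2,000
simulations per scenario.  These sizes were chosen so each property is
measured with useful precision while the whole suite stays convenient to
run routinely.

# Numerical choices and edge cases

* Genepop reading accepts 2- and 3-digit allele coding (detected from
  code width); writing always emits canonical 3-digit codes.  A
  half-missing genotype ("000095") is recorded as wholly missing — a
  diploid call cannot be half-observed for any estimator used here — and
  counted in the parse report.
* Loci contributing zero total variance are dropped from theta's sums;
  a theta of a population with itself is defined as 0 for matrix
  displays.
* The EM for null alleles stops on a log-likelihood change below
  $10^{-10}$ or a parameter change below $10^{-8}$; the latter matters
  when the null frequency decays geometrically toward zero and the
  likelihood flattens.
* Weibull fits report `converged = FALSE` instead of failing when the
  curvature is singular; ED50 CIs are then `NA`.
* Mantel regressions drop zero-distance pairs when logging distance and
  report how many were dropped.

# Known limitations

The AMOVA permutation scheme moves *populations* among regions for F_RT,
which can split a state's populations across regions in a permuted
replicate; state groups are then re-formed within regions.  The
alternative (permuting whole states) uses very few exchangeable units at
this design (6 states) and was not adopted.  The corrected-theta route
for null alleles adjusts frequencies but keeps observed heterozygote
counts, which is consistent at small null frequencies (the regime the
study design implies) but is not a full re-estimation of the components
under the null-allele model.  ABC parameter estimation (as opposed to
model choice) is out of scope.
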