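#' Adjust survival for the replicate-greenhouse effect
#'
#' Fits survival on the replicate indicator by maximum-likelihood logistic
#' regression and returns response-scale residuals re-centred by adding the
#' grand mean survival, so the adjusted values have the same overall mean
#' as the raw data while the between-greenhouse shift is removed.  If any
#' replicate has all-identical outcomes the logistic fit is separated and
#' the raw values are returned with a warning.
#'
#' @param table phenotype `data.frame` with columns `survival` and
#'   `replicate` (at least two replicate labels).
#' @return the table with an extra column `adjusted`.
#' @export
adjust_for_replicate <- function(table) {
  if (length(unique(table$replicate)) < 2L)
    stop("need >= 2 replicate labels to adjust")
  rates <- tapply(table$survival, table$replicate, mean)
  if (any(rates %in% c(0, 1))) {
    warning("a replicate has all-identical outcomes (separation); ",
            "falling back to raw survival")
    table$adjusted <- as.numeric(table$survival)
    return(table)
  }
  fit <- stats::glm(survival ~ factor(replicate), family = stats::binomial,
                    data = table)
  table$adjusted <- stats::residuals(fit, type = "response") +
    mean(table$survival)
  table
}

#' Fit the four-parameter Weibull dose-response curve
#'
#' Survival as a function of dose is modelled as
#' `Y(x) = d + (c - d) exp(-exp(b (ln x - ln e)))` with upper asymptote
#' `c = Y(0)`, lower asymptote `d = Y(Inf)`, slope `b > 0` and dose-scale
#' parameter `e`.  Binary responses are fit by maximum binomial likelihood;
#' continuous (replicate-adjusted) responses by (weighted) least squares.
#' Optimization is multi-start from five deterministic initializations
#' spanning the dose range, ties broken by objective then by smaller `b`.
#'
#' @param doses dose vector (kg a.i./ha); dose 0 is handled as the
#'   `x -> 0` limit `Y(0) = c`.  At least four distinct positive doses are
#'   required.
#' @param responses survival responses, binary 0/1 or adjusted values
#'   (clamped into `[0, 1]`).
#' @param weights optional nonnegative case weights (least-squares mode).
#' @param mode `"auto"` picks `"binomial"` for all-binary responses and
#'   `"ls"` otherwise.
#' @param scope label recorded in the fit (`species`, `region`, `state` or
#'   `population`).
#' @return an object of class `weibull_fit`: parameters `c`, `d`, `b`,
#'   `e`, `ed50_abs`, covariance of `(log e, b)`, log-likelihood /
#'   objective, `converged` flag and `scope`.
#' @export
fit_weibull <- function(doses, responses, weights = NULL,
                        mode = c("auto", "binomial", "ls"),
                        scope = "species") {
  mode <- match.arg(mode)
  keep <- !is.na(doses) & !is.na(responses)
  x <- doses[keep]
  y <- pmin(pmax(responses[keep], 0), 1)
  w <- if (is.null(weights)) rep(1, length(x)) else weights[keep]
  if (length(unique(x[x > 0])) < 4L)
    stop("need >= 4 distinct positive doses to fit 4 parameters")
  binary <- all(y %in% c(0, 1))
  if (mode == "auto") mode <- if (binary) "binomial" else "ls"
  if (mode == "binomial" && !binary)
    stop("binomial mode requires binary responses")
  n_obs <- length(x)

  # collapse to per-dose sufficient statistics: the binomial likelihood
  # and the least-squares estimates depend on the data only through the
  # weighted response mean per dose (the dropped within-dose SS is a
  # constant, added back for the residual variance below)
  grp <- match(x, sort(unique(x)))
  wsum <- as.vector(tapply(w, grp, sum))
  ybar <- as.vector(tapply(w * y, grp, sum)) / wsum
  within_ss <- sum(w * (y - ybar[grp])^2)
  x <- sort(unique(x))
  y <- ybar
  w <- wsum

  # theta = (eta_c, eta_d, log b, log e); c = plogis(eta_c),
  # d = c * plogis(eta_d) enforces 0 <= d < c <= 1, b > 0, e > 0
  unpack <- function(th) {
    cc <- stats::plogis(th[1])
    list(c = cc, d = cc * stats::plogis(th[2]), b = exp(th[3]),
         e = exp(th[4]))
  }
  obj <- function(th) {
    p <- unpack(th)
    mu <- weibull_curve(x, p$c, p$d, p$b, p$e)
    if (mode == "binomial") {
      mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
      -sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
    } else {
      sum(w * (y - mu)^2)
    }
  }
  # deterministic inits: e spans the positive-dose range, b spans slopes
  pos <- sort(unique(x[x > 0]))
  e0 <- stats::quantile(pos, c(0.15, 0.35, 0.5, 0.65, 0.85), names = FALSE)
  b0 <- c(1, 2, 4, 1, 2)
  c0 <- min(max(mean(y[x == min(x)]), 0.2), 0.99)
  d0 <- min(max(mean(y[x == max(x)]), 1e-3), 0.9 * c0)
  starts <- lapply(seq_along(e0), function(i)
    c(stats::qlogis(c0), stats::qlogis(d0 / c0), log(b0[i]), log(e0[i])))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch({
      f1 <- stats::optim(st, obj, method = "Nelder-Mead",
                         control = list(maxit = 3000, reltol = 1e-13))
      stats::optim(f1$par, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-13))
    }, error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 &&
         fit$par[3] < best$par[3])) best <- fit
  }
  if (is.null(best)) stop("Weibull optimization failed from all starts")
  th <- best$par
  p <- unpack(th)
  converged <- best$convergence == 0 && all(is.finite(th))

  # covariance of (log e, b) from the inverse curvature at the optimum
  vc <- matrix(NA_real_, 2, 2, dimnames = list(c("loge", "b"),
                                               c("loge", "b")))
  vc_ok <- tryCatch({
    H <- stats::optimHess(th, obj)
    V <- if (mode == "binomial") solve(H) else {
      s2 <- (best$value + within_ss) / max(1, n_obs - 4L)
      2 * s2 * solve(H)
    }
    # transform from (log b, log e) block: d b / d log b = b
    J <- diag(c(1, p$b))
    vc <- J %*% V[c(4, 3), c(4, 3)] %*% t(J)
    dimnames(vc) <- list(c("loge", "b"), c("loge", "b"))
    TRUE
  }, error = function(e) FALSE)
  if (!vc_ok) converged <- converged && FALSE

  structure(list(c = p$c, d = p$d, b = p$b, e = p$e,
                 ed50_abs = p$e * log(2)^(1 / p$b),
                 vcov_loge_b = vc, objective = best$value, mode = mode,
                 converged = converged, scope = scope, n = n_obs),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "weibull_fit [%s, %s]: c=%.4g d=%.4g b=%.4g e=%.4g ED50=%.4g (n=%d%s)\n",
    x$scope, x$mode, x$c, x$d, x$b, x$e, x$ed50_abs, x$n,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Predict survival from a fitted Weibull curve
#' @param object a `weibull_fit`
#' @param doses doses at which to evaluate the curve
#' @param ... unused
#' @return predicted survival
#' @export
predict.weibull_fit <- function(object, doses, ...) {
  weibull_curve(doses, object$c, object$d, object$b, object$e)
}

#' ED50 of a fitted dose-response curve, with delta-method CI
#'
#' The absolute ED50 solves `Y(x) = (c + d) / 2`; in closed form
#' `ED50 = e (ln 2)^(1/b)`.  The confidence interval comes from the delta
#' method on `(ln e, b)` applied to `ln ED50`.
#'
#' @param fit a converged [fit_weibull()] result.
#' @param level confidence level.
#' @return list with `ed50`, `lower`, `upper`.
#' @export
ed50 <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "weibull_fit"))
  if (fit$b <= 0) stop("non-decreasing curve: b must be positive")
  est <- fit$e * log(2)^(1 / fit$b)
  V <- fit$vcov_loge_b
  if (anyNA(V)) return(list(ed50 = est, lower = NA_real_, upper = NA_real_))
  L <- log(log(2))
  grad <- c(1, -L / fit$b^2) # d ln ED50 / d (ln e, b)
  se <- sqrt(max(0, drop(t(grad) %*% V %*% grad)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(ed50 = est, lower = est * exp(-z * se), upper = est * exp(z * se))
}

#' Nonparametric bootstrap CI for species-level survival
#'
#' Resamples populations with replacement `B` times and takes the
#' percentile interval of the mean of population mean survivals.
#'
#' @param pop_means numeric vector of per-population mean survival.
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param dose dose at which the means were computed (recorded only).
#' @return list with `mean`, `lower`, `upper`, `B`, `dose`.
#' @export
bootstrap_species_ci <- function(pop_means, B = 1000L, seed = 1L,
                                 dose = NA_real_) {
  stopifnot(length(pop_means) >= 2L, B >= 1L)
  set.seed(seed)
  n <- length(pop_means)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  stat <- rowMeans(matrix(pop_means[idx], nrow = B))
  qs <- unname(stats::quantile(stat, c(0.025, 0.975)))
  list(mean = mean(pop_means), lower = qs[1], upper = qs[2],
       B = as.integer(B), dose = dose)
}

#' Classify populations against the species confidence interval
#'
#' A population is `above` if its mean survival exceeds the upper CI
#' bound, `below` if under the lower bound, `within` otherwise (bounds
#' inclusive).
#'
#' @param pop_means named numeric vector of population mean survival.
#' @param species_ci result of [bootstrap_species_ci()].
#' @return `data.frame` with columns `population`, `mean`, `label`.
#' @export
classify_populations <- function(pop_means, species_ci) {
  if (is.null(names(pop_means)))
    names(pop_means) <- seq_along(pop_means)
  label <- ifelse(pop_means > species_ci$upper, "above",
                  ifelse(pop_means < species_ci$lower, "below", "within"))
  data.frame(population = names(pop_means), mean = unname(pop_means),
             label = unname(label), stringsAsFactors = FALSE)
}

#' Dose-response fits at one or several grouping scopes
#'
#' Driver over [adjust_for_replicate()] and [fit_weibull()]: fits the
#' species curve and, when requested, per-region/state/population curves,
#' returning a tidy table of parameters and ED50 intervals.
#'
#' @param pheno phenotype table; needs `region`/`state` columns (see
#'   [attach_metadata()]) for those scopes.
#' @param by one of `"species"`, `"region"`, `"state"`, `"population"`.
#' @param adjust adjust for the replicate effect first (default TRUE);
#'   when FALSE raw binary survival is fit by binomial likelihood.
#' @return `data.frame`: scope, group, c, d, b, e, ed50, lower, upper,
#'   converged.
#' @export
ed50_table <- function(pheno, by = "species", adjust = TRUE) {
  by <- match.arg(by, c("species", "region", "state", "population"))
  if (adjust) {
    pheno <- adjust_for_replicate(pheno)
    resp <- pheno$adjusted
    mode <- "ls"
  } else {
    resp <- pheno$survival
    mode <- "binomial"
  }
  groups <- if (by == "species") list(species = seq_len(nrow(pheno)))
            else split(seq_len(nrow(pheno)), pheno[[by]])
  rows <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    fit <- tryCatch(fit_weibull(pheno$dose[i], resp[i], mode = mode,
                                scope = by),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(scope = by, group = g, c = NA, d = NA, b = NA,
                        e = NA, ed50 = NA, lower = NA, upper = NA,
                        converged = FALSE))
    ci <- ed50(fit)
    data.frame(scope = by, group = g, c = fit$c, d = fit$d, b = fit$b,
               e = fit$e, ed50 = ci$ed50, lower = ci$lower,
               upper = ci$upper, converged = fit$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
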