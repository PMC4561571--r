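## Geographic analyses: great-circle distances, Moran's I correlograms,
## Mantel isolation-by-distance regressions, and principal coordinates.

#' Great-circle distance matrix (km)
#'
#' Haversine distances on a sphere of radius 6371.0 km.
#'
#' @param coords `data.frame` or matrix with columns `lat`, `lon`
#'   (degrees); row names or a `population` column give labels.
#' @return symmetric `dist_matrix` in km with zero diagonal.
#' @export
haversine_km <- function(coords) {
  coords <- as.data.frame(coords)
  labels <- if (!is.null(coords$population)) coords$population else
    rownames(coords)
  if (any(abs(coords$lat) > 90) || any(abs(coords$lon) > 180))
    stop("invalid coordinates")
  n <- nrow(coords)
  pts <- cbind(coords$lon, coords$lat)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    d <- geosphere::distHaversine(pts[i, , drop = FALSE],
                                  pts[(i + 1):n, , drop = FALSE],
                                  r = 6371000) / 1000
    D[i, (i + 1):n] <- d
    D[(i + 1):n, i] <- d
  }
  structure(D, class = c("dist_matrix", "matrix"), kind = "geographic_km")
}

#' Pairwise resistance contrast matrix
#'
#' Entry `(i, j)` is `|s_i - s_j|`, the absolute difference in
#' per-population survival — the "delta resistance" metric ordinated to
#' ask whether resistant populations cluster.
#'
#' @param pop_survival named vector of per-population survival in
#'   `[0, 1]`.
#' @return symmetric `dist_matrix` (kind `delta_resistance`).
#' @export
delta_resistance <- function(pop_survival) {
  if (any(pop_survival < 0 | pop_survival > 1, na.rm = TRUE))
    stop("survival must be in [0, 1]")
  D <- abs(outer(pop_survival, pop_survival, "-"))
  dimnames(D) <- list(names(pop_survival), names(pop_survival))
  structure(D, class = c("dist_matrix", "matrix"),
            kind = "delta_resistance")
}

#' Moran's I correlogram with permutation tests
#'
#' For each distance class, binary weights `w_ij = 1` iff the pair's
#' distance falls in the class, and
#' `I = (n / W) sum w_ij (x_i - xbar)(x_j - xbar) / sum (x_i - xbar)^2`.
#' The permutation null mean is `-1/(n-1)`; the two-sided p-value is the
#' proportion of value permutations whose `|I - E[I]|` reaches the
#' observed one.  Default classes put a first break at 64.4 km (40 miles,
#' the local scale of interest) followed by deciles of the remaining
#' pairwise distances.
#'
#' @param values numeric vector (e.g. per-population survival), `>= 4`
#'   with nonzero variance.
#' @param geo geographic `dist_matrix` (km).
#' @param class_breaks_km upper class bounds; `NULL` for the default.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return `data.frame` per class: bounds, `n_pairs`, `I`, `p`, `W`;
#'   attribute `expected` is `-1/(n-1)`.
#' @export
moran_correlogram <- function(values, geo, class_breaks_km = NULL,
                              n_perm = 999L, seed = 1L) {
  n <- length(values)
  if (n < 4L) stop("need >= 4 values")
  if (stats::var(values) == 0) stop("constant values: zero variance")
  dv <- geo[upper.tri(geo)]
  if (is.null(class_breaks_km)) {
    first <- 64.4
    rest <- dv[dv > first]
    qs <- if (length(rest)) unique(stats::quantile(rest, seq(0.1, 1, 0.1),
                                                   names = FALSE)) else c()
    class_breaks_km <- c(first, qs)
  }
  breaks <- sort(unique(c(0, class_breaks_km, max(dv) + 1e-9)))
  cls <- matrix(cut(as.vector(unclass(geo)), breaks = breaks,
                    labels = FALSE), n, n)
  moran_i <- function(x, wsel) {
    xc <- x - mean(x)
    num <- sum(wsel * outer(xc, xc))
    (n / sum(wsel)) * num / sum(xc^2)
  }
  e_i <- -1 / (n - 1)
  set.seed(seed)
  perms <- replicate(n_perm, sample(n))
  out <- list()
  for (k in seq_len(length(breaks) - 1L)) {
    wsel <- !is.na(cls) & cls == k
    diag(wsel) <- FALSE
    npairs <- sum(wsel) / 2
    if (npairs == 0) {
      out[[k]] <- data.frame(lower_km = breaks[k], upper_km = breaks[k + 1],
                             n_pairs = 0, I = NA_real_, p = NA_real_,
                             W = 0)
      next
    }
    iobs <- moran_i(values, wsel)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      ip <- moran_i(values[perms[, b]], wsel)
      if (abs(ip - e_i) >= abs(iobs - e_i) - 1e-12) cnt <- cnt + 1L
    }
    out[[k]] <- data.frame(lower_km = breaks[k], upper_km = breaks[k + 1],
                           n_pairs = npairs, I = iobs,
                           p = (1 + cnt) / (1 + n_perm), W = sum(wsel))
  }
  res <- do.call(rbind, out)
  attr(res, "expected") <- e_i
  attr(res, "n") <- n
  res
}

#' Mantel isolation-by-distance regression
#'
#' Least-squares slope and Pearson correlation between transformed
#' genetic and geographic distances over unordered pairs, with a
#' one-sided (positive association) Mantel permutation test that jointly
#' permutes rows and columns of the genetic matrix.  The standard
#' transform regresses `F_ST / (1 - F_ST)` on `ln` km.
#'
#' @param genetic genetic `dist_matrix` (e.g. pairwise F_ST or chord).
#' @param geo geographic `dist_matrix` (km).
#' @param transform `"linearized_fst_vs_ln_km"`, `"chord_vs_ln_km"` (both
#'   log the distance; the first also linearizes F_ST) or `"none"`.
#' @param n_perm permutations (default 9999).
#' @param seed integer seed.
#' @return list: `slope`, `intercept`, `r`, `p`, `n_pairs`,
#'   `excluded_pairs` (zero-distance pairs dropped when logging).
#' @export
mantel_ibd <- function(genetic, geo,
                       transform = c("linearized_fst_vs_ln_km",
                                     "chord_vs_ln_km", "none"),
                       n_perm = 9999L, seed = 1L) {
  transform <- match.arg(transform)
  if (!all(dim(genetic) == dim(geo))) stop("matrix dimension mismatch")
  n <- nrow(geo)
  if (n < 4L) stop("need >= 4 populations")
  g <- if (transform == "linearized_fst_vs_ln_km")
    linearized_fst(unclass(genetic)) else unclass(genetic)
  x <- unclass(geo)
  ut <- upper.tri(x)
  mask <- ut & is.finite(g)
  excluded <- 0L
  if (transform != "none") {
    excluded <- sum(ut & x <= 0)
    mask <- mask & x > 0
    x <- suppressWarnings(log(x))
  }
  xv <- x[mask]; gv <- g[mask]
  fit <- stats::lm(gv ~ xv)
  r_obs <- stats::cor(xv, gv)
  set.seed(seed)
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    pidx <- sample(n)
    gp <- g[pidx, pidx]
    rp <- stats::cor(xv, gp[mask])
    if (!is.na(rp) && rp >= r_obs - 1e-12) cnt <- cnt + 1L
  }
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), r = r_obs,
       p = (1 + cnt) / (1 + n_perm), n_pairs = sum(mask),
       excluded_pairs = excluded)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Gower double-centering of `-D^2/2` followed by eigendecomposition.
#' Proportions of variation are computed over positive eigenvalues only;
#' negative eigenvalues are reported as diagnostics, uncorrected.
#'
#' @param dist a symmetric `dist_matrix` with zero diagonal.
#' @param n_axes number of axes to return (default 2).
#' @return list of class `pcoa_result`: `coords` (items x axes),
#'   `eigenvalues` (all, decreasing), `proportion` (per returned axis,
#'   of the positive-eigenvalue total), `negative` (diagnostics).
#' @export
pcoa <- function(dist, n_axes = 2L) {
  D <- unclass(as.matrix(dist))
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (all(D == 0)) {
    return(structure(list(
      coords = matrix(0, n, n_axes,
                      dimnames = list(rownames(D), NULL)),
      eigenvalues = rep(0, n), proportion = rep(0, n_axes),
      negative = numeric(0)), class = "pcoa_result"))
  }
  cs <- stats::cmdscale(D, k = min(n_axes, n - 1), eig = TRUE)
  eig <- cs$eig
  pos <- eig[eig > 1e-12]
  coords <- cs$points
  if (ncol(coords) < n_axes)
    coords <- cbind(coords, matrix(0, n, n_axes - ncol(coords)))
  structure(list(coords = coords[, seq_len(n_axes), drop = FALSE],
                 eigenvalues = eig,
                 proportion = eig[seq_len(n_axes)] / sum(pos),
                 negative = eig[eig < -1e-12]),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d items, %d axes returned; axis %% variation: %s\n",
              nrow(x$coords), ncol(x$coords),
              paste(sprintf("%.1f%%", 100 * x$proportion), collapse = ", ")))
  if (length(x$negative))
    cat(sprintf("  %d negative eigenvalues (min %.3g)\n",
                length(x$negative), min(x$negative)))
  invisible(x)
}
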