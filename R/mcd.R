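#' Minimum covariance determinant estimate of location and scatter
#'
#' Finds (exactly for small problems, by the FAST-MCD C-step search
#' otherwise) the size-`h` subset of the rows of `points` whose sample
#' covariance matrix has minimal determinant, and returns the subset's
#' mean and covariance as a robust estimate of the bulk of the data.
#' Geometrically, this is the minimum-volume covariance ellipsoid over
#' all half-samples, which makes the estimate insensitive to up to
#' `n - h` arbitrary outliers.
#'
#' The reported covariance is the raw subset covariance multiplied by
#' the usual consistency factor `alpha / P(chisq[d+2] <= q(alpha, d))`
#' (`alpha = h/n`), which makes it estimate the underlying covariance
#' without bias at the normal model, and then by `scale_factor`.
#' `det` is the determinant of the *raw* subset covariance, i.e. the
#' quantity the search minimises.
#'
#' @param points numeric matrix, `n x d` (`d = 2` for cytometry channel
#'   pairs). Needs `n >= 2 (d + 1)` and non-collinear points.
#' @param h size of the subset; default `floor((n + d + 1) / 2)`, the
#'   classical "half of all data points".
#' @param scale_factor extra multiplier on the covariance (default 1).
#' @param seed integer seed for the random subset starts.
#' @param method `"auto"` enumerates all `choose(n, h)` subsets when
#'   there are at most `exhaustive_limit` of them and uses the C-step
#'   search otherwise; `"exhaustive"` and `"cstep"` force one route.
#' @param n_starts number of random `(d+1)`-point starting subsets for
#'   the C-step search (default 500).
#' @param n_best number of most promising candidates iterated to full
#'   convergence (default 10).
#' @param exhaustive_limit largest subset count enumerated under
#'   `method = "auto"` (default 5000).
#' @return an object of class `mcd_estimate`: `center`, `cov` (scaled),
#'   `cov_raw`, `det`, `h`, `n`, `d`, `support` (row indices of the
#'   optimal subset), `scale_factor`, `consistency`.
#' @export
fit_mcd <- function(points, h = NULL, scale_factor = 1, seed = 1L,
                    method = c("auto", "cstep", "exhaustive"),
                    n_starts = 500L, n_best = 10L,
                    exhaustive_limit = 5000) {
  method <- match.arg(method)
  if (!is.matrix(points)) points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points); d <- ncol(points)
  if (n < 2 * (d + 1)) {
    stopf("fit_mcd needs at least %d points for d=%d (got %d)",
          2 * (d + 1), d, n)
  }
  if (anyNA(points)) stopf("fit_mcd: points must not contain missing values")
  h_min <- floor((n + d + 1) / 2)
  if (is.null(h)) h <- h_min
  h <- as.integer(h)
  if (h < h_min || h > n) {
    stopf("h must be in [%d, %d] (got %d)", h_min, n, h)
  }
  if (!is.numeric(scale_factor) || scale_factor <= 0) {
    stopf("`scale_factor` must be positive")
  }

  if (method == "auto") {
    method <- if (choose(n, h) <= exhaustive_limit) "exhaustive" else "cstep"
  }
  best <- if (method == "exhaustive") {
    mcd_exhaustive(points, h)
  } else {
    with_seed(seed, mcd_cstep_search(points, h, n_starts, n_best))
  }
  scale_ref <- prod(diag(best$cov) + .Machine$double.eps)
  if (!is.finite(best$det) || best$det <= 1e-12 * scale_ref) {
    stopf("degenerate MCD fit: best subset covariance is singular %s",
          "(collinear points or constant channel?)")
  }
  alpha <- h / n
  consistency <- if (h == n) 1 else {
    alpha / stats::pchisq(stats::qchisq(alpha, df = d), df = d + 2)
  }
  structure(list(center = best$center,
                 cov = best$cov * consistency * scale_factor,
                 cov_raw = best$cov,
                 det = best$det,
                 h = h, n = n, d = d,
                 support = sort(best$support),
                 scale_factor = scale_factor,
                 consistency = consistency,
                 method = method),
            class = "mcd_estimate")
}

#' @export
print.mcd_estimate <- function(x, ...) {
  cat(sprintf("<mcd_estimate> n=%d d=%d h=%d (%s search)\n",
              x$n, x$d, x$h, x$method))
  cat("  center:", paste(signif(x$center, 5), collapse = ", "), "\n")
  cat(sprintf("  raw subset covariance determinant: %.6g\n", x$det))
  invisible(x)
}

#' Robust (Mahalanobis) distances to an MCD estimate
#'
#' @param est an `mcd_estimate`.
#' @param points numeric matrix with `est$d` columns.
#' @return vector of Mahalanobis distances (not squared) computed with
#'   the scaled covariance.
#' @export
mcd_distances <- function(est, points) {
  stopifnot(inherits(est, "mcd_estimate"))
  if (!is.matrix(points)) points <- as.matrix(points)
  if (ncol(points) != est$d) stopf("points have wrong dimension")
  sqrt(stats::mahalanobis(points, est$center, est$cov))
}

#' Exclude agglomerates (doublets) by robust height/width gating
#'
#' Agglomerates — two or more particles measured as one event — carry an
#' inflated pulse width relative to height. For each configured channel
#' pair (default `FSC-H`/`FSC-W` and `SSC-H`/`SSC-W`) a robust bivariate
#' normal is fitted with [fit_mcd()] and each event's Mahalanobis
#' distance to it is computed; an event is kept only if it passes the
#' cutoff on *every* pair.
#'
#' The robust fit assumes an approximately elliptical cloud, so the pair
#' values are asinh-transformed before fitting by default (raw pulse
#' signals are log-normal and skewed); set `pre_transform = "none"` to
#' fit on raw values. For large tables the estimator is fitted on a
#' random subsample of `fit_subsample` events and the distances are then
#' evaluated for all events.
#'
#' @param table an [event_table] containing all pair channels (raw,
#'   untransformed values).
#' @param pairs list of length-2 character vectors of channel names.
#' @param cutoff Mahalanobis distance threshold; either a number or the
#'   string `"chi2_0.975"` (default), meaning
#'   `sqrt(qchisq(0.975, df = 2)) ~= 2.716`, the standard robust-distance
#'   convention. `Inf` keeps everything.
#' @param seed integer seed (subset starts and fitting subsample).
#' @param scale_factor passed to [fit_mcd()] (default 1).
#' @param fit_subsample fit the estimator on at most this many events
#'   (default 10000).
#' @param pre_transform `"asinh"` (default) or `"none"`.
#' @param cofactor asinh cofactor for `pre_transform = "asinh"`.
#' @param n_starts random starts for the C-step search, passed to
#'   [fit_mcd()].
#' @return an object of class `singlet_mask`: logical `keep` of length
#'   `n_events(table)`, `pair_estimates` (named list of `mcd_estimate`),
#'   `distances` (events x pairs matrix), `cutoff`.
#' @export
exclude_agglomerates <- function(table,
                                 pairs = list(c("FSC-H", "FSC-W"),
                                              c("SSC-H", "SSC-W")),
                                 cutoff = "chi2_0.975",
                                 seed = 1L,
                                 scale_factor = 1,
                                 fit_subsample = 10000L,
                                 pre_transform = c("asinh", "none"),
                                 cofactor = 1,
                                 n_starts = 500L) {
  stopifnot(inherits(table, "event_table"))
  pre_transform <- match.arg(pre_transform)
  if (identical(cutoff, "chi2_0.975")) {
    cutoff <- sqrt(stats::qchisq(0.975, df = 2))
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stopf("`cutoff` must be a positive number or \"chi2_0.975\"")
  }
  if (!length(pairs)) stopf("at least one channel pair is required")
  all_ch <- unique(unlist(pairs))
  missing_ch <- setdiff(all_ch, channels(table))
  if (length(missing_ch)) {
    stopf("gating channel(s) not in table: %s",
          paste(missing_ch, collapse = ", "))
  }
  n <- n_events(table)
  keep <- rep(TRUE, n)
  est_list <- list()
  dist_mat <- matrix(NA_real_, n, length(pairs))
  pair_names <- vapply(pairs, paste, "", collapse = "/")
  colnames(dist_mat) <- pair_names
  fit_idx <- if (n > fit_subsample) {
    sort(with_seed(derive_seed(seed, 1L), sample.int(n, fit_subsample)))
  } else {
    seq_len(n)
  }
  for (j in seq_along(pairs)) {
    x <- channel_values(table, pairs[[j]], drop = FALSE)
    if (pre_transform == "asinh") x <- asinh(x / cofactor)
    est <- fit_mcd(x[fit_idx, , drop = FALSE], scale_factor = scale_factor,
                   seed = seed, n_starts = n_starts)
    d_j <- mcd_distances(est, x)
    dist_mat[, j] <- d_j
    keep <- keep & (d_j <= cutoff)
    est_list[[pair_names[j]]] <- est
  }
  structure(list(keep = keep, pair_estimates = est_list,
                 distances = dist_mat, cutoff = cutoff,
                 pre_transform = pre_transform),
            class = "singlet_mask")
}

#' @export
print.singlet_mask <- function(x, ...) {
  cat(sprintf("<singlet_mask> kept %d / %d events (%.1f%%), cutoff %.3f\n",
              sum(x$keep), length(x$keep),
              100 * mean(x$keep), x$cutoff))
  invisible(x)
}

# -- internal ---------------------------------------------------------------

subset_stats <- function(points, idx) {
  x <- points[idx, , drop = FALSE]
  ctr <- colMeans(x)
  cv <- stats::cov(x)
  list(center = ctr, cov = cv, det = det(cv), support = idx)
}

mcd_exhaustive <- function(points, h) {
  n <- nrow(points)
  combos <- utils::combn(n, h)
  best <- NULL
  for (j in seq_len(ncol(combos))) {
    st <- subset_stats(points, combos[, j])
    if (is.null(best) || st$det < best$det) best <- st
  }
  best
}

# One concentration step: given a location/scatter, take the h points
# with smallest Mahalanobis distance. Each step provably does not
# increase the covariance determinant.
c_step <- function(points, h, center, cov) {
  d2 <- stats::mahalanobis(points, center, cov)
  idx <- order(d2)[seq_len(h)]
  subset_stats(points, idx)
}

mcd_cstep_search <- function(points, h, n_starts, n_best) {
  n <- nrow(points); d <- ncol(points)
  candidates <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    idx <- sample.int(n, d + 1)
    st <- subset_stats(points, idx)
    # enlarge degenerate starting subsets until the covariance is
    # invertible (or we run out of points)
    while (!is.finite(st$det) || st$det < .Machine$double.eps &&
             length(idx) < n) {
      idx <- unique(c(idx, sample.int(n, 1)))
      if (length(idx) >= n) break
      st <- subset_stats(points, idx)
    }
    if (!is.finite(st$det) || st$det <= 0) next
    for (k in 1:2) st <- c_step(points, h, st$center, st$cov)
    candidates[[s]] <- st
  }
  candidates <- Filter(Negate(is.null), candidates)
  if (!length(candidates)) {
    stopf("degenerate MCD fit: no non-singular starting subset found")
  }
  dets <- vapply(candidates, `[[`, 0, "det")
  top <- candidates[order(dets)[seq_len(min(n_best, length(candidates)))]]
  best <- NULL
  for (st in top) {
    repeat {
      nxt <- c_step(points, h, st$center, st$cov)
      if (nxt$det >= st$det - 1e-12 * abs(st$det)) break
      st <- nxt
    }
    if (is.null(best) || st$det < best$det) best <- st
  }
  best
}
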