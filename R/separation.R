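#' Stain-separation statistics from a two-component fit
#'
#' For a univariate two-component mixture fitted to a stained sample
#' containing two populations — the higher-signal population (HP) and
#' the lower-signal population (LP) — staining quality is scored by the
#' distance between the fitted means,
#' \deqn{\mu_{HP-LP} = \mu_{HP} - \mu_{LP},}
#' and the pooled standard deviation,
#' \deqn{\sigma_{HP-LP} = \sqrt{(\sigma_{HP}^2 + \sigma_{LP}^2)/2}.}
#' A large mean distance relative to the pooled spread means the dye and
#' channel resolve the two populations well.
#'
#' @param model a fitted [gmm] with exactly `g = 2` components in
#'   `d = 1`; the higher-mean component is HP by convention (components
#'   are mean-sorted, so HP is component 2).
#' @param channel optional channel name for the report (defaults to the
#'   model's `dims`).
#' @param dye optional dye label for the report.
#' @return an object of class `separation_report`: `mu_LP`, `mu_HP`,
#'   `sigma_LP`, `sigma_HP`, `lambda_LP`, `lambda_HP`, `mu_diff`,
#'   `sigma_pooled`, `threshold` (`NA` until [find_threshold()] is
#'   called), `channel`, `dye`.
#' @export
#' @examples
#' x <- c(rnorm(500, 2, 0.3), rnorm(500, 5, 0.3))
#' separation_metrics(fit_gmm(x, g = 2))
separation_metrics <- function(model, channel = NULL, dye = NA_character_) {
  stopifnot(inherits(model, "gmm"))
  if (model$g != 2L || model$d != 1L) {
    stopf("separation_metrics requires a univariate 2-component model %s",
          sprintf("(got g=%d, d=%d)", model$g, model$d))
  }
  mu <- model$means[, 1]
  sd_ <- sqrt(vapply(model$covariances, function(s) as.matrix(s)[1, 1], 0))
  lam <- model$weights
  # components are sorted by ascending mean: 1 = LP, 2 = HP
  structure(list(mu_LP = mu[1], mu_HP = mu[2],
                 sigma_LP = sd_[1], sigma_HP = sd_[2],
                 lambda_LP = lam[1], lambda_HP = lam[2],
                 mu_diff = mu[2] - mu[1],
                 sigma_pooled = sqrt((sd_[2]^2 + sd_[1]^2) / 2),
                 threshold = NA_real_,
                 channel = channel %||% (model$dims[1] %||% NA_character_),
                 dye = dye),
            class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat("<separation_report>",
      if (!is.na(x$dye)) sprintf("dye=%s", x$dye) else "",
      if (!is.na(x$channel)) sprintf("channel=%s", x$channel) else "", "\n")
  cat(sprintf("  LP: mu=%.4f sd=%.4f lambda=%.3f\n",
              x$mu_LP, x$sigma_LP, x$lambda_LP))
  cat(sprintf("  HP: mu=%.4f sd=%.4f lambda=%.3f\n",
              x$mu_HP, x$sigma_HP, x$lambda_HP))
  cat(sprintf("  mu_diff=%.4f  sigma_pooled=%.4f  threshold=%s\n",
              x$mu_diff, x$sigma_pooled,
              if (is.na(x$threshold)) "unset" else sprintf("%.4f", x$threshold)))
  invisible(x)
}

#' Threshold between the two fitted populations
#'
#' The inter-population threshold is where the two fitted component
#' densities cross: the root of
#' `f(x) = lambda_HP N(x; mu_HP, sigma_HP) - lambda_LP N(x; mu_LP, sigma_LP)`
#' (the higher-signal component minus the lower-signal one), located
#' with [stats::uniroot()] inside the open interval between the two
#' component means. With `weighted = FALSE` the mixing proportions are
#' dropped and the unit-weight densities are intersected instead.
#'
#' With unequal component variances the difference can have more than
#' one root between the means; the root closest to the midpoint is
#' returned and a warning notes the multiplicity. The threshold is a
#' visualization/QC aid: three-population classification never uses it.
#'
#' @param model a fitted [gmm] with `g = 2`, `d = 1` and strictly
#'   distinct means.
#' @param tol absolute root tolerance (default 1e-8).
#' @param weighted use the lambda-weighted densities (default `TRUE`).
#' @return the threshold (a number strictly between the two means).
#' @export
find_threshold <- function(model, tol = 1e-8, weighted = TRUE) {
  stopifnot(inherits(model, "gmm"))
  if (model$g != 2L || model$d != 1L) {
    stopf("find_threshold requires a univariate 2-component model")
  }
  mu <- model$means[, 1]
  sd_ <- sqrt(vapply(model$covariances, function(s) as.matrix(s)[1, 1], 0))
  lam <- if (weighted) model$weights else c(1, 1)
  if (any(model$weights <= 0)) stopf("component weights must be positive")
  if (mu[1] >= mu[2]) {
    stopf("degenerate model: component means coincide (mu = %.6g)", mu[1])
  }
  f <- function(x) {
    lam[2] * stats::dnorm(x, mu[2], sd_[2]) -
      lam[1] * stats::dnorm(x, mu[1], sd_[1])
  }
  grid <- seq(mu[1], mu[2], length.out = 512L)
  fv <- f(grid)
  sgn <- sign(fv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  exact <- which(fv == 0)
  roots <- grid[exact]
  for (i in flips) {
    r <- stats::uniroot(f, lower = grid[i], upper = grid[i + 1],
                        tol = tol)$root
    roots <- c(roots, r)
  }
  roots <- sort(unique(roots))
  if (!length(roots)) {
    stopf(paste0("no density crossover between the component means ",
                 "(mu_LP=%.4g, mu_HP=%.4g): one component engulfs the ",
                 "other; no threshold is defined"), mu[1], mu[2])
  }
  if (length(roots) > 1L) {
    warning(sprintf(
      "multiple density crossovers in (%.4g, %.4g); returning the one closest to the midpoint",
      mu[1], mu[2]), call. = FALSE)
  }
  mid <- mean(mu)
  roots[which.min(abs(roots - mid))]
}

#' Export separation reports as a tidy data frame
#'
#' One row per report, machine-readable twin of a dye-comparison
#' figure: columns `sample_id`, `dye`, `channel`, `mu_LP`, `mu_HP`,
#' `sigma_LP`, `sigma_HP`, `lambda_LP`, `lambda_HP`, `mu_diff`,
#' `sigma_pooled`, `threshold`.
#'
#' @param reports a `separation_report` or list of them.
#' @param sample_ids optional character vector of sample ids.
#' @return a data.frame.
#' @export
separation_table <- function(reports, sample_ids = NULL) {
  if (inherits(reports, "separation_report")) reports <- list(reports)
  if (is.null(sample_ids)) sample_ids <- rep(NA_character_, length(reports))
  do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(sample_id = sample_ids[i], dye = r$dye, channel = r$channel,
               mu_LP = r$mu_LP, mu_HP = r$mu_HP,
               sigma_LP = r$sigma_LP, sigma_HP = r$sigma_HP,
               lambda_LP = r$lambda_LP, lambda_HP = r$lambda_HP,
               mu_diff = r$mu_diff, sigma_pooled = r$sigma_pooled,
               threshold = r$threshold, stringsAsFactors = FALSE)
  }))
}
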