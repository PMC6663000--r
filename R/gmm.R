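#' Fit a Gaussian mixture model by expectation-maximization
#'
#' Models the data as a weighted sum of `g` Gaussian components and fits
#' weights, means and (co)variances by EM. Each prototype is the centre
#' of a Gaussian density whose covariance determines the spread and
#' shape of the cluster; in one dimension the components have unequal
#' variances, in `d > 1` dimensions each component carries a full
#' covariance matrix.
#'
#' Initialization is deterministic: for `d = 1` the components are
#' seeded at the `g` quantile midpoints of the data; for `d > 1` a
#' fixed-seed k-means partition supplies the starting parameters. Given
#' `seed` and `init`, the fit is fully reproducible and invariant to row
#' order.
#'
#' @param x numeric vector (d = 1) or `n x d` matrix.
#' @param g number of components (`n > g * (d + 1)` required).
#' @param init `"auto"` (quantile for d = 1, k-means otherwise),
#'   `"quantile"`, or `"kmeans"`.
#' @param tol relative log-likelihood convergence tolerance
#'   (default 1e-8).
#' @param max_iter maximum EM iterations (default 1000).
#' @param seed integer seed (used by the k-means initialization only).
#' @param dims optional channel names for the columns of `x`.
#' @param var_floor_frac variance floor as a fraction of the overall
#'   data variance (default 1e-6); a component whose covariance drops
#'   below the floor raises a degeneracy error rather than collapsing
#'   silently.
#' @return an object of class `gmm` with elements `g`, `d`, `weights`,
#'   `means` (`g x d`, rows sorted by ascending first-dimension mean),
#'   `covariances` (list of `d x d` matrices), `log_likelihood`,
#'   `trace` (per-iteration log-likelihood), `n_iter`, `converged`,
#'   `dims`, `n`.
#' @export
#' @examples
#' x <- c(rnorm(300, 0, 0.5), rnorm(300, 10, 0.5))
#' fit <- fit_gmm(x, g = 2)
#' fit$means
fit_gmm <- function(x, g, init = c("auto", "quantile", "kmeans"),
                    tol = 1e-8, max_iter = 1000L, seed = 1L,
                    dims = NULL, var_floor_frac = 1e-6) {
  init <- match.arg(init)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1)
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); d <- ncol(x)
  if (anyNA(x)) stopf("fit_gmm: data must not contain missing values")
  g <- as.integer(g)
  if (g < 1L) stopf("g must be >= 1")
  if (n <= g * (d + 1)) {
    stopf("too few observations: need n > g*(d+1) = %d, got %d",
          g * (d + 1), n)
  }
  if (!is.numeric(tol) || tol <= 0) stopf("`tol` must be > 0")
  if (is.null(dims)) dims <- colnames(x)

  overall_var <- mean(apply(x, 2, stats::var))
  var_floor <- var_floor_frac * overall_var
  if (!is.finite(var_floor) || var_floor <= 0) {
    stopf("degenerate data: overall variance is zero")
  }

  if (init == "auto") init <- if (d == 1L) "quantile" else "kmeans"
  par <- if (init == "quantile") {
    if (d != 1L) stopf("quantile initialization requires d = 1")
    gmm_init_quantile(x, g)
  } else {
    gmm_init_kmeans(x, g, seed)
  }

  w <- par$weights; mu <- unname(as.matrix(par$means))
  sig <- lapply(par$covariances, unname)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  resp <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    # E-step (log-space for numerical stability)
    logd <- matrix(0, n, g)
    for (k in seq_len(g)) {
      logd[, k] <- log(w[k]) + log_dmvnorm(x, mu[k, ], sig[[k]])
    }
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(logd - lse)

    rel <- abs(ll - ll_old) / (abs(ll_old) + 1e-10)
    if (is.finite(ll_old) && rel < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll

    # M-step
    nk <- colSums(resp)
    if (any(nk < 1e-10)) {
      stopf("component collapse: component %d has vanishing weight %s",
            which.min(nk), "(try fewer components or another init)")
    }
    w <- nk / n
    for (k in seq_len(g)) {
      mu[k, ] <- colSums(resp[, k] * x) / nk[k]
      xc <- sweep(x, 2, mu[k, ])
      s_k <- crossprod(xc * resp[, k], xc) / nk[k]
      ev_min <- min(eigen(s_k, symmetric = TRUE, only.values = TRUE)$values)
      if (ev_min < var_floor) {
        stopf(paste0("component collapse: component %d variance fell below ",
                     "the floor (%.3g < %.3g); the data may have fewer than ",
                     "g = %d resolvable clusters"),
              k, ev_min, var_floor, g)
      }
      sig[[k]] <- s_k
    }
  }

  ord <- order(mu[, 1])
  model <- structure(list(g = g, d = d,
                          weights = w[ord],
                          means = mu[ord, , drop = FALSE],
                          covariances = sig[ord],
                          log_likelihood = trace[length(trace)],
                          trace = trace,
                          n_iter = iter,
                          converged = converged,
                          dims = dims,
                          n = n,
                          init = init),
                     class = "gmm")
  model
}

#' @export
print.gmm <- function(x, ...) {
  cat(sprintf("<gmm> g=%d, d=%d, n=%d, logLik=%.4f (%s after %d iter)\n",
              x$g, x$d, x$n, x$log_likelihood,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  for (k in seq_len(x$g)) {
    cat(sprintf("  comp %d: lambda=%.4f mean=(%s) sd=(%s)\n", k,
                x$weights[k],
                paste(signif(x$means[k, ], 5), collapse = ", "),
                paste(signif(sqrt(diag(as.matrix(x$covariances[[k]]))), 5),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Mixture density of a fitted model
#'
#' Evaluates `sum_k lambda_k N(x; mu_k, Sigma_k)`.
#'
#' @param model a fitted `gmm`.
#' @param x numeric vector of points (d = 1) or an `m x d` matrix / a
#'   single length-`d` vector (d > 1).
#' @return numeric vector of nonnegative densities.
#' @export
mixture_density <- function(model, x) {
  stopifnot(inherits(model, "gmm"))
  x <- as_model_matrix(model, x)
  dens <- numeric(nrow(x))
  for (k in seq_len(model$g)) {
    dens <- dens + model$weights[k] *
      exp(log_dmvnorm(x, model$means[k, ], model$covariances[[k]]))
  }
  dens
}

#' Posterior component membership probabilities
#'
#' @param model a fitted `gmm`.
#' @param x points as in [mixture_density()].
#' @return `m x g` matrix of posterior probabilities (rows sum to 1).
#' @export
gmm_posterior <- function(model, x) {
  stopifnot(inherits(model, "gmm"))
  x <- as_model_matrix(model, x)
  logd <- matrix(0, nrow(x), model$g)
  for (k in seq_len(model$g)) {
    logd[, k] <- log(model$weights[k]) +
      log_dmvnorm(x, model$means[k, ], model$covariances[[k]])
  }
  m <- apply(logd, 1, max)
  p <- exp(logd - m)
  p / rowSums(p)
}

#' Serialize / restore a mixture model as JSON
#'
#' @param model a fitted `gmm`.
#' @param path optional file path; when `NULL` the JSON string is
#'   returned instead.
#' @return `gmm_to_json`: the JSON string (invisibly when written to a
#'   file); `gmm_from_json`: the restored `gmm`.
#' @export
gmm_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "gmm"))
  obj <- list(g = model$g, d = model$d, weights = model$weights,
              means = model$means,
              covariances = lapply(model$covariances, as.matrix),
              log_likelihood = model$log_likelihood,
              n_iter = model$n_iter, converged = model$converged,
              dims = model$dims, n = model$n, init = model$init)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname gmm_to_json
#' @param json a JSON string or path to a JSON file produced by
#'   [gmm_to_json()].
#' @export
gmm_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  covs <- obj$covariances
  if (is.array(covs)) {
    covs <- lapply(seq_len(dim(covs)[1]), function(k) {
      matrix(covs[k, , ], obj$d, obj$d)
    })
  } else if (is.list(covs)) {
    covs <- lapply(covs, function(m) matrix(unlist(m), obj$d, obj$d))
  }
  structure(list(g = obj$g, d = obj$d, weights = obj$weights,
                 means = matrix(obj$means, obj$g, obj$d),
                 covariances = covs,
                 log_likelihood = obj$log_likelihood,
                 trace = NULL, n_iter = obj$n_iter,
                 converged = obj$converged,
                 dims = obj$dims, n = obj$n, init = obj$init),
            class = "gmm")
}

# -- internal ---------------------------------------------------------------

as_model_matrix <- function(model, x) {
  if (is.vector(x) && is.numeric(x)) {
    x <- if (model$d == 1L) matrix(x, ncol = 1) else {
      if (length(x) != model$d) {
        stopf("point has length %d but model has d=%d", length(x), model$d)
      }
      matrix(x, nrow = 1)
    }
  }
  x <- as.matrix(x)
  if (ncol(x) != model$d) {
    stopf("data has %d columns but model has d=%d", ncol(x), model$d)
  }
  x
}

# Log multivariate normal density via the Cholesky factor.
log_dmvnorm <- function(x, mean, cov) {
  cov <- as.matrix(cov)
  d <- ncol(x)
  ch <- tryCatch(chol(cov), error = function(e) {
    stopf("singular component covariance in density evaluation")
  })
  xc <- sweep(x, 2, mean)
  z <- backsolve(ch, t(xc), transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

gmm_init_quantile <- function(x, g) {
  v <- x[, 1]
  probs <- (2 * seq_len(g) - 1) / (2 * g)
  mu <- matrix(stats::quantile(v, probs, names = FALSE), ncol = 1)
  s0 <- stats::sd(v) / g
  list(weights = rep(1 / g, g), means = mu,
       covariances = replicate(g, matrix(s0^2, 1, 1), simplify = FALSE))
}

gmm_init_kmeans <- function(x, g, seed) {
  # the partition is only a starting point for EM, so a kmeans run that
  # stops at iter.max is fine — muffle its convergence warning
  km <- with_seed(seed, withCallingHandlers(
    stats::kmeans(x, centers = g, nstart = 10, iter.max = 100,
                  algorithm = "Lloyd"),
    warning = function(w) {
      if (grepl("did not converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  d <- ncol(x)
  covs <- vector("list", g)
  fallback <- stats::cov(x) / g^2
  for (k in seq_len(g)) {
    xk <- x[km$cluster == k, , drop = FALSE]
    covs[[k]] <- if (nrow(xk) > d + 1) stats::cov(xk) else fallback
    if (!all(is.finite(covs[[k]])) ||
          min(eigen(covs[[k]], symmetric = TRUE,
                    only.values = TRUE)$values) <= 0) {
      covs[[k]] <- fallback
    }
  }
  list(weights = pmax(km$size, 1) / sum(pmax(km$size, 1)),
       means = km$centers, covariances = covs)
}
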