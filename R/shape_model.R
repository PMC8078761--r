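# Gaussian mixture model of worm posture (full covariances, EM).
# The mixture is the generative model from which arbitrarily many training
# postures are sampled; fitting uses k-means initialization and a small
# diagonal regularization so that EM remains stable in 100 dimensions.

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# log N(x; mu, sigma) for all rows of X, via Cholesky
.log_dmvnorm <- function(X, mu, chol_upper) {
  Y <- sweep(X, 2, mu)
  Z <- forwardsolve(t(chol_upper), t(Y))
  maha <- colSums(Z^2)
  logdet <- 2 * sum(log(diag(chol_upper)))
  -0.5 * (ncol(X) * log(2 * pi) + logdet + maha)
}

#' Fit a Gaussian mixture model of worm postures
#'
#' Expectation-Maximization fit of a full-covariance Gaussian mixture to a
#' library of centerline angle vectors. Initialization is by k-means on the
#' shape library; a small constant is added to covariance diagonals so that
#' components with few members stay well conditioned.
#'
#' @param shapes matrix with one angle vector per row (continuous along the
#'   body, global rotation removed).
#' @param n_components number of mixture components. The package default of
#'   270 matches a library of roughly 15000 postures; scale it down with the
#'   library.
#' @param seed integer seed controlling initialization (the fit is
#'   deterministic given the seed).
#' @param max_iter,tol EM stopping rule: stop when the mean log-likelihood
#'   improves by less than `tol` (default 1e-3) or after `max_iter`
#'   iterations.
#' @param reg value added to covariance diagonals at every M step.
#' @return an object of class `worm_shape_model`: `weights` (simplex),
#'   `means` (k x N), `covariances` (list of N x N matrices), `loglik`,
#'   `aic`, `df`, `n_iter`, `converged`, `seed`.
#' @export
fit_shape_model <- function(shapes, n_components = 270, seed = 1,
                            max_iter = 100, tol = 1e-3, reg = 1e-6) {
  X <- as.matrix(shapes)
  n <- nrow(X); N <- ncol(X); k <- n_components
  if (n < k) stop("need at least as many shapes as components")

  # k-means initialization -> hard responsibilities
  resp <- matrix(0, n, k)
  if (k == 1) {
    resp[, 1] <- 1
  } else {
    km <- withr::with_seed(seed,
      tryCatch(stats::kmeans(X, centers = k, iter.max = 30, nstart = 1),
               error = function(e) NULL))
    if (is.null(km)) {
      cl <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
    } else cl <- km$cluster
    resp[cbind(seq_len(n), cl)] <- 1
  }

  weights <- numeric(k); means <- matrix(0, k, N)
  chols <- vector("list", k)
  m_step <- function(resp) {
    nk <- colSums(resp)
    nk[nk < 1e-10] <- 1e-10
    weights <<- nk / n
    for (j in seq_len(k)) {
      means[j, ] <<- colSums(X * resp[, j]) / nk[j]
      Y <- sweep(X, 2, means[j, ]) * sqrt(resp[, j])
      S <- crossprod(Y) / nk[j]
      diag(S) <- diag(S) + reg
      chols[[j]] <<- chol(S)
    }
  }
  m_step(resp)

  loglik <- -Inf; converged <- FALSE; it <- 0
  logdens <- matrix(0, n, k)
  while (it < max_iter) {
    it <- it + 1
    for (j in seq_len(k))
      logdens[, j] <- log(weights[j]) + .log_dmvnorm(X, means[j, ], chols[[j]])
    lse <- logsumexp_rows(logdens)
    ll <- sum(lse)
    resp <- exp(logdens - lse)
    m_step(resp)
    if ((ll - loglik) / n < tol && is.finite(loglik)) {
      loglik <- ll; converged <- TRUE; break
    }
    loglik <- ll
  }

  df <- (k - 1) + k * N + k * N * (N + 1) / 2
  covs <- lapply(chols, crossprod)
  structure(list(
    weights = weights, means = means, covariances = covs,
    n_components = k, loglik = loglik, df = df,
    aic = 2 * df - 2 * loglik, n_iter = it, converged = converged,
    seed = seed, schema_version = 1L
  ), class = "worm_shape_model")
}

#' @export
print.worm_shape_model <- function(x, ...) {
  cat("Worm posture Gaussian mixture:", x$n_components, "components,",
      ncol(x$means), "angles\n")
  cat(sprintf("  log-likelihood %.1f  AIC %.1f  (%d EM iterations%s)\n",
              x$loglik, x$aic, x$n_iter,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Select the number of mixture components by AIC
#'
#' Fits the shape mixture for each candidate component count and returns the
#' Akaike information criterion curve (`AIC = 2k - 2 logL` with `k` the free
#' parameter count) together with its argmin. Individual fit failures are
#' recorded as `NA` rather than aborting the scan.
#'
#' @inheritParams fit_shape_model
#' @param candidates integer vector of component counts to try.
#' @return list with `best` (the argmin candidate), `aic` (named vector) and
#'   `fits` (list of fitted models, `NULL` where fitting failed).
#' @export
select_components_aic <- function(shapes, candidates, seed = 1, ...) {
  if (length(candidates) == 0) stop("no candidate component counts")
  fits <- lapply(candidates, function(k)
    tryCatch(fit_shape_model(shapes, n_components = k, seed = seed, ...),
             error = function(e) NULL))
  aic <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$aic,
                numeric(1))
  names(aic) <- as.character(candidates)
  if (all(is.na(aic))) stop("all candidate fits failed")
  list(best = candidates[which.min(aic)], aic = aic, fits = fits)
}

#' Sample postures from a fitted shape model
#'
#' @param model a `worm_shape_model`.
#' @param n number of centerlines to draw.
#' @param seed integer seed; identical seeds give identical draws.
#' @return matrix with one sampled angle vector per row (continuous along
#'   the body; wrap with [wrap_angles()] if principal-interval angles are
#'   needed).
#' @export
sample_shapes <- function(model, n, seed = 1) {
  stopifnot(n >= 1)
  N <- ncol(model$means)
  withr::with_seed(seed, {
    comp <- sample.int(model$n_components, n, replace = TRUE,
                       prob = model$weights)
    out <- matrix(0, n, N)
    for (j in unique(comp)) {
      idx <- which(comp == j)
      R <- chol(model$covariances[[j]])
      Z <- matrix(stats::rnorm(length(idx) * N), length(idx), N)
      out[idx, ] <- sweep(Z %*% R, 2, model$means[j, ], `+`)
    }
    out
  })
}

#' Log-density of centerlines under a shape model
#' @param model a `worm_shape_model`.
#' @param shapes matrix of angle vectors (rows).
#' @return log mixture density per row.
#' @export
shape_model_logdensity <- function(model, shapes) {
  X <- as.matrix(shapes)
  k <- model$n_components
  logdens <- matrix(0, nrow(X), k)
  for (j in seq_len(k))
    logdens[, j] <- log(model$weights[j]) +
      .log_dmvnorm(X, model$means[j, ], chol(model$covariances[[j]]))
  logsumexp_rows(logdens)
}

#' Balance a shape library by turning amplitude
#'
#' Subsamples a shape library so that the third eigenworm projection `a_3`
#' (turning amplitude) is approximately uniform over its occupied range,
#' preventing the mixture fit from being dominated by the abundant uncoiled
#' postures. Implemented by inverse-frequency weighting over a histogram of
#' `a_3` (30 bins by default).
#'
#' @param shapes matrix of angle vectors (rows).
#' @param basis a `worm_eigenbasis` with at least 3 components.
#' @param n_out number of shapes to keep (default: as many as supplied).
#' @param n_bins histogram bin count for the weighting.
#' @param seed integer seed.
#' @return integer vector of selected row indices (with replacement when
#'   `n_out` exceeds the bin-balanced supply).
#' @export
subsample_uniform_a3 <- function(shapes, basis, n_out = nrow(shapes),
                                 n_bins = 30, seed = 1) {
  a3 <- project_modes(as.matrix(shapes), basis)[, 3]
  br <- seq(min(a3), max(a3), length.out = n_bins + 1)
  bin <- findInterval(a3, br, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  w <- 1 / counts[bin]
  withr::with_seed(seed,
    sample.int(length(a3), n_out, replace = TRUE, prob = w / sum(w)))
}

#' Save / load a fitted shape model
#'
#' The model is stored as a single serialized archive with a schema version,
#' so that fitted mixtures can be reused across pipeline runs.
#'
#' @param model a `worm_shape_model`.
#' @param path file path.
#' @return `load_shape_model` returns the model; `save_shape_model` its path.
#' @export
save_shape_model <- function(model, path) {
  stopifnot(inherits(model, "worm_shape_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_shape_model
#' @export
load_shape_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "worm_shape_model") ||
      is.null(model$schema_version))
    stop("not a serialized worm shape model")
  model
}
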