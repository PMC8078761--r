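# Two-state (general k) hidden Markov model with diagonal-covariance
# Gaussian emissions, fitted by Baum-Welch with a k-means start; no HMM
# package ships with the supported stack, so the forward-backward and
# Viterbi recursions are implemented here in log space.

.hmm_log_emissions <- function(X, means, vars) {
  k <- nrow(means)
  out <- matrix(0, nrow(X), k)
  for (j in seq_len(k))
    out[, j] <- rowSums(stats::dnorm(X, mean = matrix(means[j, ], nrow(X),
                                                      ncol(X), byrow = TRUE),
                                     sd = matrix(sqrt(vars[j, ]), nrow(X),
                                                 ncol(X), byrow = TRUE),
                                     log = TRUE))
  out
}

#' Fit a Gaussian-emission hidden Markov model
#'
#' Baum-Welch (EM) fit of a `k`-state HMM with diagonal-covariance Gaussian
#' emissions, initialized by k-means; the state path is decoded with the
#' Viterbi algorithm.
#'
#' @param X numeric matrix, one observation vector per row (time ordered).
#' @param n_states number of hidden states (default 2).
#' @param seed integer seed (k-means initialization).
#' @param max_iter,tol EM stopping rule on the log-likelihood.
#' @param var_floor lower bound on emission variances.
#' @return object of class `gaussian_hmm`: `transition` (row-stochastic),
#'   `init`, `means`, `vars`, `loglik`, `states` (Viterbi path),
#'   `posterior`.
#' @export
gaussian_hmm <- function(X, n_states = 2, seed = 1, max_iter = 100,
                         tol = 1e-6, var_floor = 1e-8) {
  X <- as.matrix(X)
  Tn <- nrow(X); d <- ncol(X); k <- n_states
  if (all(apply(X, 2, stats::var) < 1e-12)) {
    warning("constant input; a single state describes the data")
  }
  km <- withr::with_seed(seed,
    tryCatch(stats::kmeans(X, centers = k, nstart = 3),
             error = function(e) NULL))
  if (is.null(km)) {
    cl <- rep_len(seq_len(k), Tn)
  } else cl <- km$cluster
  means <- t(vapply(seq_len(k), function(j)
    colMeans(X[cl == j, , drop = FALSE]), numeric(d)))
  vars <- t(vapply(seq_len(k), function(j)
    pmax(apply(X[cl == j, , drop = FALSE], 2, stats::var), var_floor),
    numeric(d)))
  vars[is.na(vars)] <- var_floor
  P <- matrix(0.1 / (k - 1), k, k); diag(P) <- 0.9
  init <- rep(1 / k, k)

  loglik <- -Inf
  for (it in seq_len(max_iter)) {
    logB <- .hmm_log_emissions(X, means, vars)
    logP <- log(P)
    # forward
    la <- matrix(-Inf, Tn, k)
    la[1, ] <- log(init) + logB[1, ]
    for (t in 2:Tn) {
      for (j in seq_len(k)) {
        v <- la[t - 1, ] + logP[, j]
        m <- max(v)
        la[t, j] <- m + log(sum(exp(v - m))) + logB[t, j]
      }
    }
    m <- max(la[Tn, ])
    ll <- m + log(sum(exp(la[Tn, ] - m)))
    # backward
    lb <- matrix(0, Tn, k)
    for (t in (Tn - 1):1) {
      for (i in seq_len(k)) {
        v <- logP[i, ] + logB[t + 1, ] + lb[t + 1, ]
        mm <- max(v)
        lb[t, i] <- mm + log(sum(exp(v - mm)))
      }
    }
    lg <- la + lb - ll
    gamma <- exp(lg)
    # transition expectations
    xi <- matrix(0, k, k)
    for (t in 1:(Tn - 1)) {
      lx <- outer(la[t, ], logB[t + 1, ] + lb[t + 1, ], `+`) + logP - ll
      xi <- xi + exp(lx)
    }
    # M step
    init <- gamma[1, ] / sum(gamma[1, ])
    P <- xi / rowSums(xi)
    for (j in seq_len(k)) {
      w <- gamma[, j] / sum(gamma[, j])
      means[j, ] <- colSums(X * w)
      vars[j, ] <- pmax(colSums((X - matrix(means[j, ], Tn, d,
                                            byrow = TRUE))^2 * w),
                        var_floor)
    }
    if (is.finite(loglik) && ll - loglik < tol) { loglik <- ll; break }
    loglik <- ll
  }

  # Viterbi decoding
  logB <- .hmm_log_emissions(X, means, vars)
  logP <- log(P)
  delta <- matrix(-Inf, Tn, k); psi <- matrix(0L, Tn, k)
  delta[1, ] <- log(init) + logB[1, ]
  for (t in 2:Tn) {
    for (j in seq_len(k)) {
      v <- delta[t - 1, ] + logP[, j]
      psi[t, j] <- which.max(v)
      delta[t, j] <- v[psi[t, j]] + logB[t, j]
    }
  }
  states <- integer(Tn)
  states[Tn] <- which.max(delta[Tn, ])
  for (t in (Tn - 1):1) states[t] <- psi[t + 1, states[t + 1]]

  structure(list(transition = P, init = init, means = means, vars = vars,
                 loglik = loglik, states = states,
                 posterior = exp(la + lb - loglik)),
            class = "gaussian_hmm")
}

#' Stationary distribution of a Markov transition matrix
#' @param P row-stochastic matrix.
#' @return probability vector `pi` with `pi %*% P = pi`.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}
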