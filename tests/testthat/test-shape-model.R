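# Gaussian mixture shape model: EM fitting, AIC model selection, sampling
# and the curvature-balanced subsampling utility.

test_that("single-component fit recovers the generating Gaussian", {
  set.seed(21)
  n <- 800; d <- 6
  mu <- runif(d, -1, 1)
  X <- matrix(rnorm(n * d, sd = 0.5), n, d)
  X <- sweep(X, 2, mu, `+`)
  fit <- fit_shape_model(X, n_components = 1, seed = 1)
  se <- 0.5 / sqrt(n)
  expect_true(all(abs(fit$means[1, ] - mu) < 3 * se + 1e-6))
  expect_equal(fit$weights, 1)
  expect_equal(mean(diag(fit$covariances[[1]])), 0.25, tolerance = 0.05)
})

test_that("two well-separated clusters give balanced weights", {
  set.seed(22)
  n <- 2000; d <- 4
  X <- rbind(matrix(rnorm(n / 2 * d, mean = 0, sd = 0.3), n / 2, d),
             matrix(rnorm(n / 2 * d, mean = 4, sd = 0.3), n / 2, d))
  fit <- fit_shape_model(X, n_components = 2, seed = 1)
  expect_equal(sort(fit$weights), c(0.5, 0.5), tolerance = 0.05)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  # covariances symmetric positive semi-definite
  for (S in fit$covariances) {
    expect_equal(S, t(S), tolerance = 1e-10)
    expect_gte(min(eigen(S, symmetric = TRUE)$values), 0)
  }
})

test_that("fitting is deterministic given the seed", {
  set.seed(23)
  X <- matrix(rnorm(600), 150, 4)
  f1 <- fit_shape_model(X, n_components = 3, seed = 9)
  f2 <- fit_shape_model(X, n_components = 3, seed = 9)
  expect_identical(f1$means, f2$means)
  expect_identical(f1$weights, f2$weights)
})

test_that("log-likelihood does not decrease with more components", {
  fix <- get_fix()
  shapes <- fixture_corpus(fix$world, n = 400, seed = 2)[, seq(1, 100, 5)]
  lls <- vapply(c(1, 2, 4), function(k)
    fit_shape_model(shapes, n_components = k, seed = 1)$loglik, numeric(1))
  expect_true(all(diff(lls) > -1e-6 * abs(lls[-1])))
})

test_that("AIC selects the true component count", {
  # 2-dim projection keeps the free-parameter count small relative to n
  set.seed(24)
  n <- 3000
  X <- rbind(matrix(rnorm(n / 2 * 2, 0, 0.4), n / 2, 2),
             matrix(rnorm(n / 2 * 2, 3, 0.4), n / 2, 2))
  sel <- select_components_aic(X, candidates = c(1, 2, 8), seed = 1)
  expect_equal(sel$best, 2)
  expect_equal(unname(which.min(sel$aic)), 2L)
  expect_true(all(sel$aic[sel$best == names(sel$aic)] <= sel$aic,
                  na.rm = TRUE))
  expect_equal(select_components_aic(X, candidates = 3, seed = 1)$best, 3)
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  set.seed(25)
  X <- rbind(matrix(rnorm(400, 0, 0.5), 200, 2),
             matrix(rnorm(400, 3, 0.5), 200, 2))
  fit <- fit_shape_model(X, n_components = 2, seed = 1)
  mc <- mclust::Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  # same means (up to label order) and similar log-likelihood
  ord <- order(fit$means[, 1]); mord <- order(mc$parameters$mean[1, ])
  expect_equal(unname(fit$means[ord, ]),
               unname(t(mc$parameters$mean)[mord, ]),
               tolerance = 0.05)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-3 * abs(mc$loglik))
})

test_that("sampling is deterministic and matches mixture moments", {
  set.seed(26)
  X <- rbind(matrix(rnorm(1000, 0, 1), 500, 2),
             matrix(rnorm(1000, 5, 1), 500, 2))
  fit <- fit_shape_model(X, n_components = 2, seed = 1)
  s1 <- sample_shapes(fit, 4000, seed = 7)
  s2 <- sample_shapes(fit, 4000, seed = 7)
  expect_identical(s1, s2)
  mix_mean <- colSums(fit$means * fit$weights)
  expect_equal(colMeans(s1), mix_mean, tolerance = 0.15)
  # total covariance = within + between
  mix_cov <- Reduce(`+`, lapply(1:2, function(j)
    fit$weights[j] * (fit$covariances[[j]] +
                        tcrossprod(fit$means[j, ] - mix_mean))))
  expect_equal(cov(s1), mix_cov, tolerance = 0.15)
  # near-degenerate component: samples concentrate at the mean
  tiny <- fit
  tiny$weights <- 1; tiny$means <- fit$means[1, , drop = FALSE]
  tiny$covariances <- list(diag(1e-12, 2)); tiny$n_components <- 1
  expect_equal(unname(sample_shapes(tiny, 3, seed = 1)[1, ]),
               unname(fit$means[1, ]), tolerance = 1e-4)
})

test_that("a3-balanced subsampling flattens the turning-mode histogram", {
  fix <- get_fix()
  basis <- fixture_eigenbasis(fix$world, n = 400, seed = 1)
  # heavily imbalanced library: mostly uncoiled, few coiled
  set.seed(27)
  n <- 4000
  U <- nemapose:::.fixture_modes(fix$world)
  a3 <- c(rnorm(round(0.9 * n), 0, 3),
          runif(n - round(0.9 * n), -25, 25))
  shapes <- cbind(rnorm(n, 0, 4), rnorm(n, 0, 4), a3) %*% t(U)
  idx <- subsample_uniform_a3(shapes, basis, n_out = 3000, seed = 1)
  a3_sub <- project_modes(shapes[idx, ], basis)[, 3]
  h <- hist(a3_sub, breaks = seq(min(a3_sub) - 1e-9, max(a3_sub) + 1e-9,
                                 length.out = 11), plot = FALSE)
  p <- chisq.test(h$counts)$p.value
  expect_gt(p, 0.01)  # flatness not rejected
})

test_that("shape models serialize and reload", {
  set.seed(28)
  X <- matrix(rnorm(400), 100, 4)
  fit <- fit_shape_model(X, n_components = 2, seed = 1)
  f <- tempfile(fileext = ".rds")
  save_shape_model(fit, f)
  back <- load_shape_model(f)
  expect_identical(back$means, fit$means)
  expect_error(suppressWarnings(load_shape_model(tempfile())))
})
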