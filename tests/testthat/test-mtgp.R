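# Shared small multi-trait problem: two kernels, three traits.
small_problem <- function(seed = 1, n = 40) {
  set.seed(seed)
  K1 <- random_psd(n, seed = seed + 100)$values
  K2 <- diag(n)
  g <- t(chol(K1 + diag(1e-8, n))) %*% matrix(rnorm(n * 3), n)
  Y <- g + matrix(rnorm(n * 3, 0, 0.5), n)
  colnames(Y) <- c("t1", "t2", "t3")
  rownames(Y) <- paste0("o", seq_len(n))
  list(Y = Y, K1 = K1, K2 = K2)
}

test_that("null responses give near-zero predictions for masked cells", {
  set.seed(3)
  n <- 30
  Y <- matrix(0, n, 2, dimnames = list(paste0("o", 1:n), c("a", "b")))
  mask <- matrix(FALSE, n, 2)
  mask[1:5, ] <- TRUE
  fit <- mtgp(Y, kernels = list(k = diag(n)), mask = mask,
              niter = 800, burnin = 300, thin = 2, seed = 4)
  pred <- predict(fit)
  expect_equal(nrow(pred), 10L)
  expect_true(all(abs(pred$prediction) <= pmax(3 * pred$mcse + 3 * pred$sd,
                                               0.3)))
})

test_that("prior-only run (everything masked) predicts the prior mean", {
  n <- 20
  Y <- matrix(NA_real_, n, 2)
  fit <- mtgp(Y, kernels = list(k = diag(n)),
              niter = 600, burnin = 200, thin = 2, seed = 5)
  expect_lt(max(abs(fit$yhat)), 1.0)
  expect_equal(mean(abs(fit$yhat)) < 0.5, TRUE)
})

test_that("noise-free data is reproduced almost exactly", {
  set.seed(6)
  n <- 50
  K <- random_psd(n, seed = 7)$values
  g <- as.vector(t(chol(K + diag(1e-8, n))) %*% rnorm(n))
  y <- 5 + g
  fit <- fit_single_trait(y, K, niter = 1500, burnin = 500, thin = 2,
                          seed = 8, fixed = list(R = matrix(1e-4)))
  expect_gt(cor(fit$effects$g[, 1], y), 0.99)
})

test_that("single-trait wrapper equals the general sampler with one trait", {
  set.seed(9)
  n <- 25
  y <- rnorm(n)
  K <- random_psd(n, seed = 10)$values
  f1 <- fit_single_trait(y, K, niter = 500, burnin = 200, thin = 2,
                         seed = 11)
  f2 <- mtgp(matrix(y, ncol = 1), kernels = list(g = K),
             niter = 500, burnin = 200, thin = 2, seed = 11)
  expect_equal(f1$yhat[, 1], f2$yhat[, 1], ignore_attr = TRUE)
})

test_that("identical seeds reproduce the draw sequence bit for bit", {
  p <- small_problem(12)
  mask <- matrix(FALSE, nrow(p$Y), 3); mask[1:4, ] <- TRUE
  a <- mtgp(p$Y, kernels = list(k1 = p$K1, k2 = p$K2), mask = mask,
            niter = 300, burnin = 100, thin = 2, seed = 99)
  b <- mtgp(p$Y, kernels = list(k1 = p$K1, k2 = p$K2), mask = mask,
            niter = 300, burnin = 100, thin = 2, seed = 99)
  expect_identical(a$Sigma_draws, b$Sigma_draws)
  expect_identical(a$R_draws, b$R_draws)
  expect_identical(a$yhat, b$yhat)
})

test_that("posterior covariance draws are symmetric positive definite", {
  p <- small_problem(13)
  fit <- mtgp(p$Y, kernels = list(k1 = p$K1), niter = 400, burnin = 100,
              thin = 2, seed = 14)
  for (i in seq_len(fit$mcmc$ndraws)) {
    s <- fit$Sigma_draws$k1[, , i]
    expect_equal(s, t(s))
    expect_gt(min(eigen(s, TRUE, TRUE)$values), 0)
    r <- fit$R_draws[, , i]
    expect_gt(min(eigen(r, TRUE, TRUE)$values), 0)
  }
})

test_that("posterior means are invariant to permuting observations", {
  p <- small_problem(15, n = 35)
  mask <- matrix(FALSE, 35, 3); mask[1:6, ] <- TRUE
  fit <- mtgp(p$Y, kernels = list(k1 = p$K1), mask = mask,
              niter = 3000, burnin = 1000, thin = 2, seed = 16)
  perm <- sample(35)
  fitp <- mtgp(p$Y[perm, ], kernels = list(k1 = p$K1[perm, perm]),
               mask = mask[perm, ], niter = 3000, burnin = 1000,
               thin = 2, seed = 17)
  back <- order(perm)
  expect_gt(cor(as.vector(fit$yhat), as.vector(fitp$yhat[back, ])), 0.995)
  expect_lt(mean(abs(fit$yhat - fitp$yhat[back, ])), 0.1)
})

test_that("with all variances forced to zero predictions collapse to the intercept", {
  p <- small_problem(18)
  mask <- matrix(FALSE, nrow(p$Y), 3); mask[1:5, ] <- TRUE
  tiny <- diag(1e-10, 3)
  fit <- mtgp(p$Y, kernels = list(k1 = p$K1, k2 = p$K2), mask = mask,
              niter = 400, burnin = 100, thin = 2, seed = 19,
              fixed = list(k1 = tiny, k2 = tiny))
  ybar <- colMeans(p$Y[-(1:5), ])
  for (j in 1:3) {
    expect_lt(max(abs(fit$yhat[1:5, j] - ybar[j])), 0.2)
  }
})

test_that("covariates with known effects are recovered", {
  set.seed(20)
  n <- 80
  X <- cbind(a = rnorm(n), b = rnorm(n))
  B <- rbind(c(2, -1), c(0.5, 1))
  Y <- X %*% B + matrix(rnorm(n * 2, 0, 0.3), n)
  colnames(Y) <- c("t1", "t2")
  fit <- mtgp(Y, kernels = list(noise = diag(n)), X = X,
              niter = 1000, burnin = 400, thin = 2, seed = 21)
  expect_lt(max(abs(fit$beta - B)), 0.25)
})

test_that("a masked duplicate of an observed record shrinks toward it", {
  # two observations with identical kernel profile; one observed, one masked
  set.seed(22)
  n <- 30
  K <- random_psd(n - 1, seed = 23)$values
  K2 <- rbind(cbind(K, K[, 1]), c(K[1, ], K[1, 1]))  # row n duplicates row 1
  y <- as.vector(t(chol(K + diag(1e-8, n - 1))) %*% rnorm(n - 1)) * 2 + 10
  y <- c(y, NA)
  fit <- fit_single_trait(y, K2, niter = 2000, burnin = 500, thin = 2,
                          seed = 24)
  pred <- predict(fit)
  stopifnot(nrow(pred) == 1L)
  lo <- min(y[1], mean(y, na.rm = TRUE)) - 0.15
  hi <- max(y[1], mean(y, na.rm = TRUE)) + 0.15
  expect_gt(pred$prediction, lo)
  expect_lt(pred$prediction, hi)
})

test_that("fit accessors expose fitted values, residuals and summaries", {
  p <- small_problem(25)
  mask <- matrix(FALSE, nrow(p$Y), 3); mask[1:3, ] <- TRUE
  fit <- mtgp(p$Y, kernels = list(k1 = p$K1), mask = mask,
              niter = 300, burnin = 100, thin = 2, seed = 26)
  expect_s3_class(fit, "mtgp")
  expect_equal(dim(fitted(fit)), dim(p$Y))
  r <- residuals(fit)
  expect_true(all(is.na(r[1:3, ])))
  expect_false(anyNA(r[-(1:3), ]))
  s <- summary(fit)
  expect_s3_class(s, "summary.mtgp")
  expect_equal(rownames(s$variances), "k1")
  cm <- genetic_correlation(fit, "k1")
  expect_equal(diag(cm), c(t1 = 1, t2 = 1, t3 = 1))
  expect_error(genetic_correlation(fit, "nope"), "unknown term")
  co <- coef(fit)
  expect_named(co, "k1")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2L)
  expect_equal(dim(sims[[1]]), dim(p$Y))
  # no masked cells -> empty prediction table
  fit0 <- mtgp(p$Y, kernels = list(k1 = p$K1), niter = 200, burnin = 100,
               thin = 2, seed = 27)
  expect_equal(nrow(predict(fit0)), 0L)
})
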