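make_parent_tab <- function(vals_m, vals_f, trait = "GY") {
  rbind(
    data.frame(entry = names(vals_m), role = "male", year = "0",
               v = unname(vals_m), stringsAsFactors = FALSE),
    data.frame(entry = names(vals_f), role = "female", year = "0",
               v = unname(vals_f), stringsAsFactors = FALSE)
  ) |> (\(d) { names(d)[4] <- trait; d })()
}

test_that("Pmean covariates are the mid-parent mean and half absolute difference", {
  ped <- data.frame(hybrid = "h1", male = "M1", female = "F1")
  tab <- make_parent_tab(c(M1 = 10), c(F1 = 6))
  x <- pmean_covariates(tab, ped)
  expect_equal(unname(x["h1", "GY_a"]), 8)
  expect_equal(unname(x["h1", "GY_d"]), 2)

  # equal parents -> zero dominance covariate
  x0 <- pmean_covariates(make_parent_tab(c(M1 = 7), c(F1 = 7)), ped)
  expect_equal(unname(x0["h1", "GY_d"]), 0)

  # swapping the parental phenotypes changes nothing
  xs <- pmean_covariates(make_parent_tab(c(M1 = 6), c(F1 = 10)), ped)
  expect_equal(xs, x)
})

test_that("parents phenotyped in several years are averaged before Eqs-style arithmetic", {
  ped <- data.frame(hybrid = "h1", male = "M1", female = "F1")
  tab <- rbind(
    data.frame(entry = "M1", role = "male", year = c("1", "2"),
               GY = c(8, 12), stringsAsFactors = FALSE),
    data.frame(entry = "F1", role = "female", year = "1", GY = 6,
               stringsAsFactors = FALSE))
  x <- pmean_covariates(tab, ped)
  expect_equal(unname(x["h1", "GY_a"]), (10 + 6) / 2)
  expect_equal(unname(x["h1", "GY_d"]), 2)
})

test_that("missing parental phenotypes fail loudly unless imputation is requested", {
  ped <- data.frame(hybrid = c("h1", "h2"), male = c("M1", "M2"),
                    female = c("F1", "F1"))
  tab <- make_parent_tab(c(M1 = 10), c(F1 = 6))   # M2 absent
  expect_error(pmean_covariates(tab, ped), "h2")
  x <- pmean_covariates(tab, ped, impute_missing = TRUE)
  expect_equal(unname(x["h2", "GY_a"]), (8 + 6) / 2)  # M2 <- mean(10, 6)
})

test_that("BV covariates apply the same construction to breeding values", {
  ped <- data.frame(hybrid = "h1", male = "M1", female = "F1")
  bvs <- list(GY = c(M1 = 1, F1 = -1))
  x <- bv_covariates(bvs, ped)
  expect_equal(unname(x["h1", "GY_a"]), 0)
  expect_equal(unname(x["h1", "GY_d"]), 1)

  # constant breeding values: additive = c, dominance = 0
  ped3 <- data.frame(hybrid = c("h1", "h2"),
                     male = c("M1", "M2"), female = c("F1", "F2"))
  xc <- bv_covariates(list(GY = c(M1 = 3, M2 = 3, F1 = 3, F2 = 3)), ped3)
  expect_equal(unname(xc[, "GY_a"]), c(3, 3))
  expect_equal(unname(xc[, "GY_d"]), c(0, 0))

  # passing breeding values through the phenotype route gives identical output
  tab <- make_parent_tab(c(M1 = 1), c(F1 = -1))
  expect_equal(unclass(bv_covariates(bvs, ped)),
               unclass(pmean_covariates(tab, ped)), ignore_attr = TRUE)
})

test_that("covariate standardization centers, scales and drops constants", {
  set.seed(8)
  x <- cbind(GY_a = rnorm(30, 5), GY_d = abs(rnorm(30)), DTF_a = rep(2, 30))
  expect_warning(s <- assemble_covariate_matrix(x), "constant")
  expect_identical(colnames(s), c("GY_a", "GY_d"))
  expect_lt(max(abs(colMeans(s))), 1e-12)
  expect_equal(unname(apply(s, 2, sd)), c(1, 1))
  expect_true(attr(s, "standardized"))
  # off switch is the identity
  expect_equal(unclass(assemble_covariate_matrix(x, standardize = FALSE)),
               x, ignore_attr = TRUE)
})

test_that("breeding values with identity kernel match the ridge closed form", {
  set.seed(15)
  n <- 40
  y <- rnorm(n, mean = 10)
  names(y) <- paste0("P", seq_len(n))
  tab <- data.frame(entry = names(y), role = "male", year = "0", GY = y,
                    stringsAsFactors = FALSE)
  gk <- kernel_matrix(diag(n), ids = names(y))
  sg <- 0.8; se <- 0.4
  # fixed variances: posterior mean is exactly (I + lambda I)^-1 (y - ybar)
  fit <- fit_single_trait(y, gk, niter = 6000, burnin = 1000, thin = 2,
                          seed = 2, fixed = list(g = matrix(sg),
                                                 R = matrix(se)))
  ridge <- (y - mean(y)) / (1 + se / sg)
  expect_gt(cor(fit$effects$g[, 1], ridge), 0.999)
  expect_lt(max(abs(fit$effects$g[, 1] - ridge)), 0.05)

  # the exported estimator (sampled variances) tracks the same solution
  bv <- estimate_breeding_values(tab, gk, "GY", niter = 2000,
                                 burnin = 500, thin = 2, seed = 2)
  expect_length(bv, n)
  expect_gt(cor(bv, ridge), 0.95)
  expect_lt(abs(mean(bv)), 0.2)
})

test_that("shrinkage limit: near-zero genetic variance forces breeding values to zero", {
  set.seed(16)
  y <- rnorm(20, 5)
  names(y) <- paste0("P", 1:20)
  gk <- kernel_matrix(diag(20), ids = names(y))
  fit <- fit_single_trait(y, gk, niter = 600, burnin = 200, thin = 2,
                          seed = 3, fixed = list(g = matrix(1e-8),
                                                 R = matrix(1)))
  expect_lt(max(abs(fit$effects$g)), 1e-2)
})

test_that("BV and Pmean additive covariates agree under strong additive signal", {
  set.seed(77)
  n_par <- 200
  w <- random_std_markers(n_par, 300, seed = 78)
  g_true <- as.vector(w$dosages %*% rnorm(300, 0, sqrt(1 / 300)))
  h2 <- 0.8
  y <- 10 + g_true + rnorm(n_par, 0, sqrt(var(g_true) * (1 - h2) / h2))
  names(y) <- w$ids
  tab <- data.frame(entry = names(y),
                    role = rep(c("male", "female"), each = n_par / 2),
                    year = "0", GY = y, stringsAsFactors = FALSE)
  ped <- data.frame(hybrid = paste0("h", 1:(n_par / 2)),
                    male = names(y)[1:(n_par / 2)],
                    female = names(y)[(n_par / 2 + 1):n_par])
  g <- ensure_psd(genomic_relationship(w))
  bv <- estimate_breeding_values(tab, g, "GY", niter = 1500, burnin = 500,
                                 thin = 2, seed = 5)
  x_bv <- bv_covariates(list(GY = bv), ped)
  x_pm <- pmean_covariates(tab, ped)
  expect_gt(cor(x_bv[, "GY_a"], x_pm[, "GY_a"]), 0.7)
})
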