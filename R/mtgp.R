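#' Eigendecompose a kernel for repeated model fits
#'
#' The sampler works in the eigenbasis of each observation-level kernel;
#' decomposing once and passing the result to several [mtgp()] calls (e.g.
#' the three covariate strategies on the same cross-validation fold) avoids
#' repeating the O(n^3) factorization. Eigenvalues below `tol` times the
#' largest (and negative ones) are truncated: the corresponding effect
#' directions are fixed at their prior mean of zero.
#'
#' @param k a `kernel_matrix` or plain symmetric matrix.
#' @param tol relative eigenvalue truncation threshold.
#' @return object of class `kernel_eigen` with fields `U` (n x r), `d` (r),
#'   `n`.
#' @export
kernel_eigen <- function(k, tol = 1e-10) {
  v <- if (inherits(k, "kernel_matrix")) k$values else as.matrix(k)
  ev <- eigen(v, symmetric = TRUE)
  dmax <- max(ev$values, 0)
  if (dmax <= 0) stop("kernel has no positive eigenvalue")
  if (min(ev$values) < -1e-8 * max(dmax, 1)) {
    stop("kernel is not positive semi-definite; run ensure_psd() first")
  }
  keep <- ev$values > tol * dmax
  structure(list(U = ev$vectors[, keep, drop = FALSE],
                 d = ev$values[keep], n = nrow(v)),
            class = "kernel_eigen")
}

# Draw from an inverse-Wishart(nu, S) via the Wishart of the inverse scale.
rinvwishart <- function(nu, S) {
  Sinv <- chol2inv(chol(S))
  Sinv <- (Sinv + t(Sinv)) / 2
  W <- stats::rWishart(1L, nu, Sinv)[, , 1L]
  out <- chol2inv(chol(W))
  (out + t(out)) / 2
}

default_mtgp_prior <- function(vy, n_terms, n_scalar) {
  # each structured term, each scalar term and the residual get an equal
  # a-priori share of the per-trait phenotypic variance
  share <- 1 / (n_terms + 1)
  t_ <- length(vy)
  list(df0 = t_ + 2,
       S0 = diag(share * vy, t_),
       df0_scalar = 5,
       s0_scalar = share * mean(vy),
       df0_R = t_ + 2,
       S0_R = diag(share * vy, t_))
}

#' Fit the multi-trait kernel mixed model by Gibbs sampling
#'
#' Fits, to an observations x traits response matrix, a sum of
#' kernel-structured random effects with matrix-variate normal priors
#' `MN(0, K_k, Sigma_k)`, optional fixed-scale covariates with a Gaussian
#' prior, and a multivariate normal residual with trait covariance `R`.
#' This is the engine behind hybrid prediction with general and specific
#' combining ability terms and their year interactions, and (with one trait
#' and one kernel) behind parental breeding-value estimation.
#'
#' The sampler cycles, in a fixed order for seed reproducibility:
#' \enumerate{
#'   \item each random-effect matrix from its matrix-variate normal full
#'     conditional, computed in the eigenbasis of its kernel (each kernel is
#'     eigendecomposed once; in that basis the rows are conditionally
#'     independent and are jointly diagonalized against `R`, so the update
#'     is fully vectorized);
#'   \item the covariate coefficient matrix from its Gaussian conditional;
#'   \item each trait covariance `Sigma_k` from an inverse-Wishart
#'     conditional (terms listed in `scalar_terms` instead use an isotropic
#'     `sigma2 * I` with a scaled-inverse-chi-squared conditional, the form
#'     used for the year main effect);
#'   \item the residual covariance `R` from an inverse-Wishart conditional;
#'   \item masked response cells from their conditional normal given the
#'     current fit (data augmentation), which is what yields predictions for
#'     untested hybrids.
#' }
#'
#' Responses are centered per trait internally (the model carries no grand
#' mean); trait means are restored in fitted values and predictions.
#'
#' @param Y numeric matrix (observations x traits); `NA` cells are treated
#'   as masked.
#' @param kernels named list of observation-level kernels: `kernel_matrix`
#'   objects, plain symmetric matrices, or `kernel_eigen` decompositions.
#' @param X optional covariate matrix (observations x q), e.g. parental
#'   covariates; given independent `N(0, beta_prior_var)` priors per
#'   coefficient.
#' @param mask logical matrix marking cells to treat as unobserved (defaults
#'   to `is.na(Y)`; any `NA` cells are always masked).
#' @param scalar_terms names of kernels whose trait covariance is restricted
#'   to `sigma2 * I`.
#' @param niter,burnin,thin chain length, burn-in and thinning.
#' @param seed integer seed; identical seed and inputs reproduce the draw
#'   sequence exactly.
#' @param prior optional list overriding the default weakly-informative
#'   prior (fields `df0`, `S0`, `df0_scalar`, `s0_scalar`, `df0_R`, `S0_R`).
#'   By default every term and the residual receive an equal share of the
#'   per-trait phenotypic variance as inverse-Wishart prior expectation with
#'   `df0 = n_traits + 2`.
#' @param fixed named list fixing variance parameters instead of sampling
#'   them: a `T x T` matrix (or scalar for `scalar_terms`) per term name,
#'   and/or `R` for the residual covariance.
#' @param beta_prior_var prior variance of each covariate coefficient.
#' @param eigen_tol relative eigenvalue truncation for kernel ranks.
#' @param verbose print progress every 500 iterations.
#' @return an object of class `mtgp`; see [predict.mtgp()],
#'   [summary.mtgp()], [coef.mtgp()].
#' @export
mtgp <- function(Y, kernels, X = NULL, mask = NULL,
                 scalar_terms = character(),
                 niter = 10000L, burnin = 5000L, thin = 5L, seed = NULL,
                 prior = NULL, fixed = list(), beta_prior_var = 1e4,
                 eigen_tol = 1e-10, verbose = FALSE) {
  Y <- as.matrix(Y)
  n <- nrow(Y); t_ <- ncol(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("trait", seq_len(t_))
  traits <- colnames(Y)
  obs_ids <- rownames(Y)
  if (is.null(mask)) mask <- matrix(FALSE, n, t_)
  mask <- mask | is.na(Y)
  if (all(mask)) {
    # prior-only run is allowed; keep variances at their priors
    Y[] <- ifelse(is.na(Y), 0, Y)
  }
  if (niter <= burnin) stop("'niter' must exceed 'burnin'")
  if (!length(kernels) || is.null(names(kernels)) ||
      any(!nzchar(names(kernels)))) {
    stop("'kernels' must be a non-empty named list")
  }
  term_names <- names(kernels)
  if (anyDuplicated(term_names)) stop("kernel term names must be unique")
  bad_sc <- setdiff(scalar_terms, term_names)
  if (length(bad_sc)) stop("unknown scalar term(s): ",
                           paste(bad_sc, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  eigs <- lapply(kernels, function(k) {
    if (inherits(k, "kernel_eigen")) k else kernel_eigen(k, tol = eigen_tol)
  })
  if (any(vapply(eigs, function(e) e$n, 0L) != n)) {
    stop("every kernel must have one row per observation")
  }

  # per-trait centering on observed cells
  ybar <- vapply(seq_len(t_), function(j) {
    obs <- !mask[, j]
    if (any(obs)) mean(Y[obs, j]) else 0
  }, 0)
  Yc <- sweep(Y, 2L, ybar, "-")
  Yc[mask] <- 0

  has_x <- !is.null(X)
  if (has_x) {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("'X' must have one row per observation")
    q <- ncol(X)
    B <- matrix(0, q, t_, dimnames = list(colnames(X), traits))
  }

  vy <- vapply(seq_len(t_), function(j) {
    obs <- !mask[, j]
    if (sum(obs) > 1L) stats::var(Y[obs, j]) else 1
  }, 0)
  vy[vy <= 0] <- 1
  n_scalar <- length(scalar_terms)
  pr <- default_mtgp_prior(vy, length(kernels), n_scalar)
  if (!is.null(prior)) pr[names(prior)] <- prior

  is_scalar <- term_names %in% scalar_terms
  Sigma <- vector("list", length(kernels)); names(Sigma) <- term_names
  for (k in seq_along(kernels)) {
    if (term_names[k] %in% names(fixed)) {
      fk <- fixed[[term_names[k]]]
      Sigma[[k]] <- if (is_scalar[k]) diag(as.numeric(fk), t_)
        else as.matrix(fk)
    } else if (is_scalar[k]) {
      Sigma[[k]] <- diag(pr$s0_scalar, t_)
    } else Sigma[[k]] <- pr$S0
  }
  R <- if ("R" %in% names(fixed)) as.matrix(fixed$R) else pr$S0_R
  fix_term <- term_names %in% names(fixed)
  fix_R <- "R" %in% names(fixed)

  ft <- lapply(eigs, function(e) matrix(0, length(e$d), t_))
  Fhat <- matrix(0, n, t_)

  # group masked rows by missingness pattern for the augmentation step
  pat <- apply(mask, 1L, function(r) paste(as.integer(r), collapse = ""))
  pat_groups <- split(seq_len(n), pat)
  pat_groups <- pat_groups[names(pat_groups) !=
                             paste(rep("0", t_), collapse = "")]

  ndraws <- length(seq.int(burnin + 1L, niter, by = thin))
  Sigma_draws <- lapply(seq_along(kernels), function(k) {
    array(NA_real_, c(t_, t_, ndraws))
  })
  names(Sigma_draws) <- term_names
  R_draws <- array(NA_real_, c(t_, t_, ndraws))
  yhat_sum <- matrix(0, n, t_); yhat_sq <- matrix(0, n, t_)
  ft_sum <- lapply(eigs, function(e) matrix(0, length(e$d), t_))
  B_sum <- if (has_x) matrix(0, q, t_) else NULL
  draw <- 0L

  for (it in seq_len(niter)) {
    cR <- chol(R)
    # (i) random-effect matrices, term by term
    for (k in seq_along(kernels)) {
      e <- eigs[[k]]
      # residual seen by term k, rotated into its eigenbasis
      Yt <- crossprod(e$U, Yc - Fhat) + ft[[k]]
      # joint diagonalization of (Sigma_k, R): R = Q Q', Sigma_k = Q L Q'
      Sstar <- backsolve(cR, t(backsolve(cR, t(Sigma[[k]]),
                                         transpose = TRUE)),
                         transpose = TRUE)
      ge <- eigen((Sstar + t(Sstar)) / 2, symmetric = TRUE)
      lam <- pmax(ge$values, 0)
      Q <- t(cR) %*% ge$vectors
      Qinv <- t(ge$vectors) %*% backsolve(cR, diag(t_), transpose = TRUE)
      Z <- Yt %*% t(Qinv)
      dl <- outer(e$d, lam)            # r x T
      shrink <- dl / (dl + 1)
      M <- Z * shrink
      Znew <- M + matrix(stats::rnorm(length(M)), nrow(M)) * sqrt(shrink)
      ft_new <- Znew %*% t(Q)
      Fhat <- Fhat + e$U %*% (ft_new - ft[[k]])
      ft[[k]] <- ft_new
    }
    # (ii) covariate coefficients
    if (has_x) {
      Eb <- Yc - Fhat + X %*% B
      Rinv <- chol2inv(cR)
      P <- kronecker(Rinv, crossprod(X)) + diag(1 / beta_prior_var, q * t_)
      cP <- chol((P + t(P)) / 2)
      rhs <- as.vector(crossprod(X, Eb) %*% Rinv)
      mu_b <- backsolve(cP, backsolve(cP, rhs, transpose = TRUE))
      b_draw <- mu_b + backsolve(cP, stats::rnorm(q * t_))
      B_new <- matrix(b_draw, q, t_)
      Fhat <- Fhat + X %*% (B_new - B)
      B <- B_new
    }
    if (!all(is.finite(Fhat))) {
      stop("divergent (non-finite) draws at iteration ", it)
    }
    # (iii) trait covariances / scalar variances
    for (k in seq_along(kernels)) {
      if (fix_term[k]) next
      e <- eigs[[k]]; fk <- ft[[k]]; r_k <- length(e$d)
      if (is_scalar[k]) {
        ss <- sum(fk^2 / e$d)
        df <- pr$df0_scalar + r_k * t_
        s2 <- (ss + pr$df0_scalar * pr$s0_scalar) / stats::rchisq(1L, df)
        Sigma[[k]] <- diag(s2, t_)
      } else {
        Sf <- crossprod(fk, fk / e$d)
        Sigma[[k]] <- rinvwishart(pr$df0 + r_k, pr$S0 + (Sf + t(Sf)) / 2)
      }
    }
    # (iv) residual covariance
    E <- Yc - Fhat
    if (!fix_R) {
      SE <- crossprod(E)
      R <- rinvwishart(pr$df0_R + n, pr$S0_R + (SE + t(SE)) / 2)
    }
    # (v) data augmentation of masked cells
    if (length(pat_groups)) {
      cR2 <- chol(R)
      for (g in seq_along(pat_groups)) {
        rows <- pat_groups[[g]]
        miss <- mask[rows[1L], ]
        if (all(miss)) {
          z <- matrix(stats::rnorm(length(rows) * t_), length(rows))
          Yc[rows, ] <- Fhat[rows, , drop = FALSE] + z %*% cR2
        } else {
          Roo <- R[!miss, !miss, drop = FALSE]
          Rmo <- R[miss, !miss, drop = FALSE]
          Rmm <- R[miss, miss, drop = FALSE]
          W <- Rmo %*% chol2inv(chol(Roo))
          cond_cov <- Rmm - W %*% t(Rmo)
          cc <- chol((cond_cov + t(cond_cov)) / 2)
          resid_o <- Yc[rows, !miss, drop = FALSE] -
            Fhat[rows, !miss, drop = FALSE]
          mu <- Fhat[rows, miss, drop = FALSE] + resid_o %*% t(W)
          z <- matrix(stats::rnorm(length(rows) * sum(miss)), length(rows))
          Yc[rows, miss] <- mu + z %*% cc
        }
      }
    }
    # record
    if (it > burnin && (it - burnin) %% thin == 0L) {
      draw <- draw + 1L
      yhat_sum <- yhat_sum + Fhat
      yhat_sq <- yhat_sq + Fhat^2
      for (k in seq_along(kernels)) {
        Sigma_draws[[k]][, , draw] <- Sigma[[k]]
        ft_sum[[k]] <- ft_sum[[k]] + ft[[k]]
      }
      R_draws[, , draw] <- R
      if (has_x) B_sum <- B_sum + B
    }
    if (verbose && it %% 500L == 0L) {
      message("iteration ", it, "/", niter)
    }
  }

  yhat_mean <- yhat_sum / ndraws
  yhat_sd <- sqrt(pmax(yhat_sq / ndraws - yhat_mean^2, 0))
  yhat <- sweep(yhat_mean, 2L, ybar, "+")
  dimnames(yhat) <- list(obs_ids, traits)
  effects <- lapply(seq_along(eigs), function(k) {
    s <- eigs[[k]]$U %*% (ft_sum[[k]] / ndraws)
    dimnames(s) <- list(obs_ids, traits); s
  })
  names(effects) <- term_names
  Sigma_mean <- lapply(Sigma_draws, function(a) {
    m <- apply(a, c(1, 2), mean); dimnames(m) <- list(traits, traits); m
  })
  R_mean <- apply(R_draws, c(1, 2), mean)
  dimnames(R_mean) <- list(traits, traits)

  structure(list(
    call = match.call(),
    traits = traits, n = n, obs_ids = obs_ids,
    Y = Y, mask = mask, trait_means = ybar,
    yhat = yhat, yhat_sd = yhat_sd,
    mcse = yhat_sd / sqrt(ndraws),
    effects = effects,
    beta = if (has_x) B_sum / ndraws else NULL,
    Sigma = Sigma_mean, Sigma_draws = Sigma_draws,
    R = R_mean, R_draws = R_draws,
    scalar_terms = scalar_terms,
    mcmc = list(niter = niter, burnin = burnin, thin = thin,
                ndraws = ndraws, seed = seed)
  ), class = "mtgp")
}

#' Single-trait kernel model
#'
#' Special case of [mtgp()] for one response vector, used for parental
#' breeding-value estimation (`y = mu + g + e` with `g ~ N(0, sigma_g^2 K)`).
#'
#' @param y numeric response vector (NA = masked).
#' @param K kernel over the observations (`kernel_matrix`, matrix or
#'   `kernel_eigen`).
#' @param ... passed to [mtgp()].
#' @return an `mtgp` fit with one trait and one random term `"g"`.
#' @export
fit_single_trait <- function(y, K, ...) {
  Y <- matrix(y, ncol = 1L, dimnames = list(names(y), "trait"))
  mtgp(Y, kernels = list(g = K), ...)
}

#' @export
print.mtgp <- function(x, ...) {
  cat(sprintf("mtgp fit: %d observations, %d trait(s), %d random term(s)\n",
              x$n, length(x$traits), length(x$Sigma)))
  cat(sprintf("  chain: %d iterations (burn-in %d, thin %d, %d draws kept)\n",
              x$mcmc$niter, x$mcmc$burnin, x$mcmc$thin, x$mcmc$ndraws))
  cat(sprintf("  masked cells: %d\n", sum(x$mask)))
  invisible(x)
}

#' Posterior summary of a fitted hybrid model
#'
#' Tabulates posterior means of the per-term trait variances and, for
#' multi-trait fits, the genetic correlation matrices implied by each trait
#' covariance.
#'
#' @param object an `mtgp` fit.
#' @param ... unused.
#' @export
summary.mtgp <- function(object, ...) {
  vars <- t(vapply(object$Sigma, diag, numeric(length(object$traits))))
  colnames(vars) <- object$traits
  out <- list(variances = vars, R = object$R,
              correlations = lapply(object$Sigma, stats::cov2cor),
              mcmc = object$mcmc)
  class(out) <- "summary.mtgp"
  out
}

#' @export
print.summary.mtgp <- function(x, ...) {
  cat("Posterior mean trait variances by term:\n")
  print(round(x$variances, 4))
  cat("\nResidual covariance R:\n")
  print(round(x$R, 4))
  invisible(x)
}

#' Posterior-mean trait correlations of a random term
#' @param object an `mtgp` fit.
#' @param term term name (e.g. `"gca_m"`).
#' @return correlation matrix from the posterior mean trait covariance.
#' @export
genetic_correlation <- function(object, term = "gca_m") {
  stopifnot(inherits(object, "mtgp"))
  if (!term %in% names(object$Sigma)) stop("unknown term: ", term)
  stats::cov2cor(object$Sigma[[term]])
}

#' @export
coef.mtgp <- function(object, ...) {
  c(object$effects, if (!is.null(object$beta)) list(beta = object$beta))
}

#' @export
fitted.mtgp <- function(object, ...) object$yhat

#' @export
residuals.mtgp <- function(object, ...) {
  r <- object$Y - object$yhat
  r[object$mask] <- NA_real_
  r
}

#' Predictions for masked response cells
#'
#' Posterior-mean predictive values (trait units, per-trait centering
#' undone) for every masked cell, with Monte Carlo standard errors.
#'
#' @param object an `mtgp` fit.
#' @param ... unused.
#' @return data frame with columns `observation`, `trait`, `prediction`,
#'   `sd`, `mcse`; empty when nothing was masked.
#' @export
predict.mtgp <- function(object, ...) {
  idx <- which(object$mask, arr.ind = TRUE)
  obs <- if (is.null(object$obs_ids)) as.character(idx[, 1L]) else
    object$obs_ids[idx[, 1L]]
  data.frame(observation = obs,
             trait = object$traits[idx[, 2L]],
             prediction = object$yhat[idx],
             sd = object$yhat_sd[idx],
             mcse = object$mcse[idx],
             stringsAsFactors = FALSE)
}

#' Trace plot of per-term trait variances
#' @param x an `mtgp` fit.
#' @param terms term names to show (default all).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mtgp <- function(x, terms = names(x$Sigma), ...) {
  tr <- sapply(terms, function(nm) {
    apply(x$Sigma_draws[[nm]], 3L, function(s) mean(diag(s)))
  })
  graphics::matplot(tr, type = "l", lty = 1,
                    xlab = "retained draw",
                    ylab = "mean trait variance", ...)
  graphics::legend("topright", legend = terms, col = seq_along(terms),
                   lty = 1, cex = 0.8, bty = "n")
  invisible(x)
}

#' Simulate responses from the posterior-mean parameters
#'
#' Draws new response matrices from the fitted model with every effect and
#' covariance fixed at its posterior mean: fitted values plus residual noise
#' with trait covariance `R`.
#'
#' @param object an `mtgp` fit.
#' @param nsim number of simulated response matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of `nsim` matrices shaped like the response.
#' @export
simulate.mtgp <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cR <- chol(object$R)
  lapply(seq_len(nsim), function(i) {
    z <- matrix(stats::rnorm(object$n * length(object$traits)), object$n)
    object$yhat + z %*% cR
  })
}
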