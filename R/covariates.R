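#' Mid-parent and parental-difference covariates
#'
#' Under the "Pmean" strategy each hybrid receives, per trait, an additive
#' covariate equal to the mean of its two parents' phenotypes,
#' `x_a = (P_M + P_F) / 2`, and a dominance covariate equal to half the
#' absolute parental difference, `x_d = |P_M - P_F| / 2`. Parents phenotyped
#' in several years are first averaged across years. Both covariates are
#' invariant to exchanging the two parents.
#'
#' @param parents phenotype data frame containing the parental rows
#'   (role `"male"` or `"female"`).
#' @param ped pedigree data frame.
#' @param traits trait names (defaults to all trait columns).
#' @param impute_missing replace missing parental trait means by the
#'   across-parent mean instead of failing.
#' @return matrix (hybrids x 2 * n_traits) with columns `<trait>_a`,
#'   `<trait>_d`, of class `covariate_matrix`.
#' @export
pmean_covariates <- function(parents, ped, traits = NULL,
                             impute_missing = FALSE) {
  pv <- parent_trait_means(parents, traits)
  parent_pair_covariates(pv$values, ped, pv$traits, impute_missing)
}

# Across-year parent phenotype means: parents x traits matrix.
parent_trait_means <- function(parents, traits = NULL) {
  check_phenos(parents)
  if (is.null(traits)) traits <- trait_names(parents)
  pp <- parents[parents$role %in% c("male", "female"), , drop = FALSE]
  if (!nrow(pp)) stop("no parental rows (role male/female) found")
  ids <- unique(pp$entry)
  vals <- matrix(NA_real_, length(ids), length(traits),
                 dimnames = list(ids, traits))
  for (tr in traits) {
    m <- tapply(pp[[tr]], pp$entry, mean, na.rm = TRUE)
    vals[names(m), tr] <- as.numeric(m)
  }
  vals[is.nan(vals)] <- NA_real_
  list(values = vals, traits = traits)
}

# Shared arithmetic for Pmean and BV covariates.
parent_pair_covariates <- function(parent_values, ped, traits,
                                   impute_missing = FALSE) {
  ped <- pedigree_table(ped)
  need <- union(ped$male, ped$female)
  have <- rownames(parent_values)
  absent <- setdiff(need, have)
  if (length(absent)) {
    add <- matrix(NA_real_, length(absent), ncol(parent_values),
                  dimnames = list(absent, colnames(parent_values)))
    parent_values <- rbind(parent_values, add)
  }
  if (anyNA(parent_values[need, traits])) {
    if (impute_missing) {
      for (tr in traits) {
        v <- parent_values[, tr]
        v[is.na(v)] <- mean(v, na.rm = TRUE)
        parent_values[, tr] <- v
      }
    } else {
      bad_par <- need[rowSums(is.na(parent_values[need, traits,
                                                  drop = FALSE])) > 0]
      bad_hy <- ped$hybrid[ped$male %in% bad_par | ped$female %in% bad_par]
      stop("missing parental values for hybrid(s): ",
           paste(utils::head(bad_hy, 5L), collapse = ", "),
           if (length(bad_hy) > 5L) ", ...",
           " (set impute_missing = TRUE to mean-impute)")
    }
  }
  pm <- parent_values[ped$male, traits, drop = FALSE]
  pf <- parent_values[ped$female, traits, drop = FALSE]
  xa <- (pm + pf) / 2
  xd <- abs(pm - pf) / 2
  out <- matrix(NA_real_, nrow(ped), 2L * length(traits),
                dimnames = list(ped$hybrid,
                                as.vector(rbind(paste0(traits, "_a"),
                                                paste0(traits, "_d")))))
  out[, paste0(traits, "_a")] <- xa
  out[, paste0(traits, "_d")] <- xd
  structure(out, class = c("covariate_matrix", "matrix", "array"),
            standardized = FALSE)
}

#' Estimate parental breeding values by a single-trait kernel model
#'
#' Fits `P = 1 mu + g + e` with `g ~ N(0, sigma_g^2 G)` over all phenotyped
#' parents (males and females jointly, phenotypes averaged across years) by
#' Gibbs sampling and returns the posterior-mean breeding values.
#'
#' @param parents phenotype data frame containing parental rows.
#' @param g_parents `kernel_matrix` (or `kernel_eigen`) over the parents,
#'   covering every phenotyped parent.
#' @param trait trait name.
#' @param niter,burnin,thin chain settings.
#' @param seed integer seed.
#' @return named numeric vector of breeding values, one per parent in the
#'   kernel (parents without phenotypes are predicted via the kernel).
#' @export
estimate_breeding_values <- function(parents, g_parents, trait,
                                     niter = 3000L, burnin = 1000L,
                                     thin = 2L, seed = NULL) {
  pv <- parent_trait_means(parents, trait)
  if (inherits(g_parents, "kernel_matrix")) {
    ids <- g_parents$ids
  } else {
    stop("'g_parents' must be a kernel_matrix over the parents")
  }
  miss <- setdiff(rownames(pv$values)[!is.na(pv$values[, trait])], ids)
  if (length(miss)) {
    stop("kernel does not cover phenotyped parent(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  y <- pv$values[match(ids, rownames(pv$values)), trait]
  names(y) <- ids
  fit <- fit_single_trait(y, g_parents, niter = niter, burnin = burnin,
                          thin = thin, seed = seed)
  bv <- fit$effects$g[, 1L]
  names(bv) <- ids
  bv
}

#' Breeding-value covariates
#'
#' The "BV" strategy applies the same mid-parent / half-difference
#' construction as [pmean_covariates()], but to estimated parental breeding
#' values instead of raw parental phenotypes.
#'
#' @param bvs named list (one element per trait) of named breeding-value
#'   vectors, as returned by [estimate_breeding_values()].
#' @param ped pedigree data frame.
#' @param traits trait names (defaults to `names(bvs)`).
#' @inheritParams pmean_covariates
#' @return a `covariate_matrix` as in [pmean_covariates()].
#' @export
bv_covariates <- function(bvs, ped, traits = names(bvs),
                          impute_missing = FALSE) {
  if (is.null(traits) || !length(traits)) stop("'bvs' must be a named list")
  ids <- unique(unlist(lapply(bvs, names)))
  vals <- matrix(NA_real_, length(ids), length(traits),
                 dimnames = list(ids, traits))
  for (tr in traits) vals[names(bvs[[tr]]), tr] <- bvs[[tr]]
  parent_pair_covariates(vals, ped, traits, impute_missing)
}

#' Standardize a covariate matrix for model entry
#'
#' Centers and scales columns to unit SD so the coefficient prior is
#' unit-free across traits measured in different units; constant columns are
#' dropped with a warning.
#'
#' @param x a `covariate_matrix` (or plain matrix).
#' @param standardize logical; `FALSE` returns the input unchanged.
#' @return standardized `covariate_matrix`.
#' @export
assemble_covariate_matrix <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (!standardize) {
    return(structure(x, class = c("covariate_matrix", "matrix", "array"),
                     standardized = FALSE))
  }
  sds <- apply(x, 2L, stats::sd)
  keep <- sds > 1e-12
  if (!all(keep)) {
    warning(sum(!keep), " constant covariate column(s) dropped: ",
            paste(colnames(x)[!keep], collapse = ", "))
  }
  x <- x[, keep, drop = FALSE]
  x <- scale(x)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  structure(as.matrix(x), class = c("covariate_matrix", "matrix", "array"),
            standardized = TRUE)
}
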