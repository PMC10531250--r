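#' Configuration for the synthetic hybrid-trial generator
#'
#' Describes a multi-year incomplete-factorial wheat hybrid trial: a small
#' set of male testers crossed to many females, three correlated traits
#' (grain yield in t/ha, days to flowering and days to heading in days),
#' partially overlapping hybrid sets across years, and the variance budget
#' of the generative model (GCA, SCA, year, kernel-by-year interaction and
#' residual terms, each expressed as a share of the per-trait phenotypic
#' variance on the standardized scale).
#'
#' The default scenario (12 males x 120 females, 3 crosses per female = 360
#' hybrids, 500 markers, 3 years) is a desk-scale rendition of a large
#' hybrid wheat program; the genetic variance shares sum to 0.6 (broad-sense
#' heritability 0.6). When `parental_signal` is `TRUE`, an additional
#' mid-parent covariate effect (`beta_a` per trait on the own-trait additive
#' covariate, `beta_d` on the dominance covariate) is added to the hybrid
#' responses, making parental phenotypes directly informative.
#'
#' @param n_males,n_females numbers of male and female parents.
#' @param crosses_per_female males mated to each female (without
#'   replacement).
#' @param n_markers SNP count.
#' @param n_years trial years.
#' @param maf_range uniform range for per-marker allele frequencies.
#' @param missing_frac fraction of marker cells set missing.
#' @param traits trait names.
#' @param trait_means,trait_sds phenotypic means and SDs in trait units.
#' @param var_shares named shares of phenotypic variance for terms
#'   `gca_m`, `gca_f`, `sca`, `year`, `gca_m_year`, `gca_f_year`,
#'   `sca_year`, `residual`; must sum to 1.
#' @param cor_g genetic trait correlation matrix (used for the GCA, SCA and
#'   interaction terms).
#' @param cor_r residual trait correlation matrix.
#' @param parent_h2 heritability of the parental per-se phenotypes.
#' @param frac_tested fraction of hybrids evaluated in each year.
#' @param overlap fraction of a year's hybrids carried over from the
#'   previous year.
#' @param parental_signal add a mid-parent covariate effect to hybrid
#'   responses.
#' @param beta_a,beta_d covariate effect sizes (standardized covariate and
#'   response scales) for the additive and dominance columns.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_males = 12L, n_females = 120L,
                       crosses_per_female = 3L,
                       n_markers = 500L, n_years = 3L,
                       maf_range = c(0.1, 0.5), missing_frac = 0.03,
                       traits = c("GY", "DTF", "DTH"),
                       trait_means = c(GY = 6, DTF = 80, DTH = 85),
                       trait_sds = c(GY = 0.8, DTF = 5, DTH = 5),
                       var_shares = c(gca_m = 0.25, gca_f = 0.20,
                                      sca = 0.15, year = 0.05,
                                      gca_m_year = 0.04, gca_f_year = 0.03,
                                      sca_year = 0.03, residual = 0.25),
                       cor_g = NULL, cor_r = NULL,
                       parent_h2 = 0.7,
                       frac_tested = 0.5, overlap = 0.3,
                       parental_signal = FALSE,
                       beta_a = 0.4, beta_d = 0) {
  t_ <- length(traits)
  if (is.null(cor_g)) {
    cor_g <- diag(t_)
    if (t_ == 3L) {
      # GY vs phenology mildly negative, flowering/heading strongly coupled
      cor_g[1, 2] <- cor_g[2, 1] <- -0.3
      cor_g[1, 3] <- cor_g[3, 1] <- -0.25
      cor_g[2, 3] <- cor_g[3, 2] <- 0.9
    }
  }
  if (is.null(cor_r)) {
    cor_r <- diag(t_)
    if (t_ == 3L) {
      cor_r[1, 2] <- cor_r[2, 1] <- 0.1
      cor_r[1, 3] <- cor_r[3, 1] <- 0.1
      cor_r[2, 3] <- cor_r[3, 2] <- 0.6
    }
  }
  cfg <- list(n_males = as.integer(n_males),
              n_females = as.integer(n_females),
              crosses_per_female = as.integer(crosses_per_female),
              n_markers = as.integer(n_markers),
              n_years = as.integer(n_years),
              maf_range = maf_range, missing_frac = missing_frac,
              traits = traits, trait_means = trait_means,
              trait_sds = trait_sds, var_shares = var_shares,
              cor_g = cor_g, cor_r = cor_r, parent_h2 = parent_h2,
              frac_tested = frac_tested, overlap = overlap,
              parental_signal = parental_signal,
              beta_a = beta_a, beta_d = beta_d)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$crosses_per_female < 1L || cfg$crosses_per_female > cfg$n_males) {
    stop("'crosses_per_female' must lie in [1, n_males]")
  }
  if (cfg$overlap < 0 || cfg$overlap > 1) stop("'overlap' must lie in [0, 1]")
  if (abs(sum(cfg$var_shares) - 1) > 1e-8) {
    stop("'var_shares' must sum to 1")
  }
  for (nm in c("cor_g", "cor_r")) {
    ev <- eigen(cfg[[nm]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) stop("'", nm, "' is not positive semi-definite")
  }
  invisible(cfg)
}

# Matrix-variate normal draw MN(0, K, Sigma) via eigen square roots.
rmatnorm <- function(K, Sigma) {
  if (inherits(K, "kernel_matrix")) K <- K$values
  if (max(abs(Sigma)) == 0) {
    return(matrix(0, nrow(K), nrow(Sigma),
                  dimnames = list(rownames(K), NULL)))
  }
  e <- eigen(K, symmetric = TRUE)
  keep <- e$values > 1e-10 * max(e$values, 1)
  L <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                                sum(keep))
  cs <- chol(Sigma + diag(1e-10, nrow(Sigma)))
  z <- matrix(stats::rnorm(sum(keep) * nrow(Sigma)), sum(keep))
  out <- L %*% z %*% cs
  rownames(out) <- rownames(K)
  out
}

#' Simulate inbred parent marker panels
#'
#' Per-marker allele frequencies are drawn uniformly from `maf_range`;
#' inbred parents carry dosage 0 or 2 with probability given by the
#' frequency. A `missing_frac` fraction of cells is set missing to exercise
#' the quality-control chain. Returns both the observed (missing-injected)
#' and the complete panels.
#'
#' @param cfg a [sim_config()].
#' @return list with `males`, `females` (raw `marker_matrix` with missing
#'   cells) and `males_complete`, `females_complete`.
#' @export
simulate_parents <- function(cfg) {
  freq <- stats::runif(cfg$n_markers, cfg$maf_range[1], cfg$maf_range[2])
  draw <- function(n, prefix) {
    d <- matrix(2 * stats::rbinom(n * cfg$n_markers, 1L,
                                  rep(freq, each = n)),
                n, cfg$n_markers,
                dimnames = list(sprintf("%s%03d", prefix, seq_len(n)),
                                paste0("snp", seq_len(cfg$n_markers))))
    d
  }
  dm <- draw(cfg$n_males, "M")
  df <- draw(cfg$n_females, "F")
  inject <- function(d) {
    if (cfg$missing_frac > 0) {
      hole <- stats::runif(length(d)) < cfg$missing_frac
      d[hole] <- NA_real_
    }
    d
  }
  list(males = marker_matrix(inject(dm)),
       females = marker_matrix(inject(df)),
       males_complete = marker_matrix(dm),
       females_complete = marker_matrix(df))
}

#' Simulate the crossing plan and hybrid genotypes
#'
#' Each female is mated to `crosses_per_female` males sampled without
#' replacement, giving an incomplete factorial. Hybrid dosages are the
#' parental means (F1 of inbreds).
#'
#' @param cfg a [sim_config()].
#' @param males,females complete parental `marker_matrix` objects.
#' @return list with `ped` (pedigree data frame) and `hybrids`
#'   (hybrid `marker_matrix`).
#' @export
simulate_crosses <- function(cfg, males, females) {
  mids <- males$ids; fids <- females$ids
  ped <- do.call(rbind, lapply(fids, function(f) {
    ms <- sample(mids, cfg$crosses_per_female)
    data.frame(hybrid = paste(ms, f, sep = "x"), male = ms, female = f,
               stringsAsFactors = FALSE)
  }))
  hd <- (males$dosages[ped$male, , drop = FALSE] +
           females$dosages[ped$female, , drop = FALSE]) / 2
  rownames(hd) <- ped$hybrid
  hyb <- marker_matrix(hd, ids = ped$hybrid, state = "raw")
  list(ped = pedigree_table(ped), hybrids = hyb)
}

# Year membership with the configured consecutive-year overlap.
assign_years <- function(hybrids, n_years, frac_tested, overlap) {
  n_per <- max(2L, round(frac_tested * length(hybrids)))
  sets <- vector("list", n_years)
  sets[[1L]] <- sample(hybrids, n_per)
  if (n_years > 1L) {
    for (y in 2:n_years) {
      n_keep <- min(round(overlap * n_per), length(sets[[y - 1L]]))
      keep <- sample(sets[[y - 1L]], n_keep)
      # fresh entries come from outside the previous year's set so the
      # realized consecutive-year overlap is exactly n_keep (when possible)
      pool <- setdiff(hybrids, sets[[y - 1L]])
      n_new <- min(n_per - n_keep, length(pool))
      fresh <- sample(pool, n_new)
      short <- n_per - n_keep - n_new
      if (short > 0) {
        fresh <- c(fresh, sample(setdiff(sets[[y - 1L]], keep), short))
      }
      sets[[y]] <- c(keep, fresh)
    }
  }
  names(sets) <- as.character(seq_len(n_years))
  sets
}

#' Simulate a complete multi-year hybrid trial
#'
#' Draws every term of the multi-trait model from its matrix-variate normal
#' distribution — male and female GCA with row covariance given by the true
#' linear genomic relationship matrices, SCA with the Hadamard hybrid
#' kernel, an isotropic year effect, the three kernel-by-year interactions,
#' and correlated residuals — sums them into hybrid BLUE-scale responses,
#' and produces parental phenotypes as parental GCA plus noise at
#' heritability `parent_h2`. All terms are generated on the standardized
#' trait scale and mapped to trait units via `trait_sds`/`trait_means`, so
#' variance shares are interpretable per trait. The returned truth allows
#' parameter-recovery and prediction tests.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of `(cfg, seed)`.
#' @return list of class `sim_trial` with `phenos` (hybrid and parent rows),
#'   `ped`, marker panels (`males`, `females` observed; `*_complete`),
#'   `hybrid_markers`, `truth` (true effect matrices, genetic values,
#'   generator seed) and `config`.
#' @export
simulate_hybrid_trial <- function(cfg = sim_config(), seed = 1L) {
  validate_sim_config(cfg)
  set.seed(seed)
  par_sim <- simulate_parents(cfg)
  crs <- simulate_crosses(cfg, par_sim$males_complete,
                          par_sim$females_complete)
  ped <- crs$ped
  t_ <- length(cfg$traits)

  # truth kernels from the complete panels (monomorphic columns silently
  # dropped: they carry no relationship information)
  std <- function(m) suppressWarnings(standardize_markers(impute_naive(m)))
  g_m <- genomic_relationship(std(par_sim$males_complete))
  g_f <- genomic_relationship(std(par_sim$females_complete))

  year_sets <- assign_years(ped$hybrid, cfg$n_years, cfg$frac_tested,
                            cfg$overlap)
  obs <- do.call(rbind, lapply(names(year_sets), function(y) {
    data.frame(hybrid = year_sets[[y]], year = y, stringsAsFactors = FALSE)
  }))
  obs <- obs[order(obs$year, obs$hybrid), , drop = FALSE]
  n <- nrow(obs)
  pidx <- match(obs$hybrid, ped$hybrid)
  obs$male <- ped$male[pidx]; obs$female <- ped$female[pidx]
  obs_ids <- paste(obs$hybrid, obs$year, sep = "@")

  hybrids <- unique(obs$hybrid)
  z_e <- incidence_matrix(obs$year, names(year_sets), obs_ids)
  z_m <- incidence_matrix(obs$male, g_m$ids, obs_ids)
  z_f <- incidence_matrix(obs$female, g_f$ids, obs_ids)
  z_h <- incidence_matrix(obs$hybrid, hybrids, obs_ids)
  first <- match(hybrids, obs$hybrid)
  h_kern <- hybrid_kernel(
    incidence_matrix(obs$male[first], g_m$ids, hybrids), g_m,
    incidence_matrix(obs$female[first], g_f$ids, hybrids), g_f)

  sh <- cfg$var_shares
  sig <- function(share) share * cfg$cor_g
  gm_eff <- rmatnorm(g_m, sig(sh[["gca_m"]]))
  gf_eff <- rmatnorm(g_f, sig(sh[["gca_f"]]))
  h_eff <- rmatnorm(h_kern, sig(sh[["sca"]]))
  beta_e <- matrix(stats::rnorm(cfg$n_years * t_, 0, sqrt(sh[["year"]])),
                   cfg$n_years, t_)
  k_gm <- expand_kernel(z_m, g_m); k_gf <- expand_kernel(z_f, g_f)
  k_h <- expand_kernel(z_h, h_kern)
  u_m <- rmatnorm(interaction_kernel(k_gm, z_e), sig(sh[["gca_m_year"]]))
  u_f <- rmatnorm(interaction_kernel(k_gf, z_e), sig(sh[["gca_f_year"]]))
  u_h <- rmatnorm(interaction_kernel(k_h, z_e), sig(sh[["sca_year"]]))
  eps <- rmatnorm(diag(n), sh[["residual"]] * cfg$cor_r)

  genetic <- z_m %*% gm_eff + z_f %*% gf_eff + z_h %*% h_eff
  y_std <- z_e %*% beta_e + genetic + u_m + u_f + u_h + eps

  # parental phenotypes: GCA plus noise at heritability parent_h2
  parent_pheno <- function(g, share) {
    noise_sd <- sqrt(share * (1 - cfg$parent_h2) / cfg$parent_h2)
    g + matrix(stats::rnorm(length(g), 0, noise_sd), nrow(g))
  }
  pm_std <- parent_pheno(gm_eff, sh[["gca_m"]])
  pf_std <- parent_pheno(gf_eff, sh[["gca_f"]])
  to_units <- function(x) {
    sweep(sweep(x, 2L, cfg$trait_sds[cfg$traits], "*"),
          2L, cfg$trait_means[cfg$traits], "+")
  }
  pm <- to_units(pm_std); pf <- to_units(pf_std)
  colnames(pm) <- colnames(pf) <- cfg$traits
  rownames(pm) <- g_m$ids; rownames(pf) <- g_f$ids

  xb <- matrix(0, n, t_)
  beta_ac <- NULL
  if (cfg$parental_signal) {
    parent_tab <- rbind(
      data.frame(entry = g_m$ids, role = "male", year = "0", pm,
                 stringsAsFactors = FALSE),
      data.frame(entry = g_f$ids, role = "female", year = "0", pf,
                 stringsAsFactors = FALSE))
    x_ac <- assemble_covariate_matrix(
      pmean_covariates(parent_tab, ped, cfg$traits))
    beta_ac <- matrix(0, ncol(x_ac), t_,
                      dimnames = list(colnames(x_ac), cfg$traits))
    for (j in seq_len(t_)) {
      a_col <- paste0(cfg$traits[j], "_a")
      d_col <- paste0(cfg$traits[j], "_d")
      if (a_col %in% rownames(beta_ac)) beta_ac[a_col, j] <- cfg$beta_a
      if (d_col %in% rownames(beta_ac)) beta_ac[d_col, j] <- cfg$beta_d
    }
    xb <- (z_h %*% x_ac[hybrids, , drop = FALSE]) %*% beta_ac
    y_std <- y_std + xb
  }

  y <- to_units(y_std)
  colnames(y) <- cfg$traits
  phenos <- rbind(
    data.frame(entry = obs$hybrid, role = "hybrid", year = obs$year, y,
               stringsAsFactors = FALSE, row.names = NULL),
    data.frame(entry = g_m$ids, role = "male", year = "0", pm,
               stringsAsFactors = FALSE, row.names = NULL),
    data.frame(entry = g_f$ids, role = "female", year = "0", pf,
               stringsAsFactors = FALSE, row.names = NULL))

  truth <- list(gca_m = gm_eff, gca_f = gf_eff, sca = h_eff,
                beta_year = beta_e, u_m = u_m, u_f = u_f, u_h = u_h,
                beta_ac = beta_ac, covariate_effect = xb,
                genetic_value = structure(genetic,
                                          dimnames = list(obs_ids,
                                                          cfg$traits)),
                cor_g = cfg$cor_g, seed = seed)
  structure(list(phenos = phenos, ped = ped,
                 males = par_sim$males, females = par_sim$females,
                 males_complete = par_sim$males_complete,
                 females_complete = par_sim$females_complete,
                 hybrid_markers = crs$hybrids,
                 truth = truth, config = cfg),
            class = "sim_trial")
}

#' @export
print.sim_trial <- function(x, ...) {
  cat(sprintf(paste0("sim_trial: %d hybrid observations over %d years, ",
                     "%d hybrids (%d males x %d females), %d markers\n"),
              sum(x$phenos$role == "hybrid"), x$config$n_years,
              nrow(x$ped), x$config$n_males, x$config$n_females,
              x$config$n_markers))
  invisible(x)
}

#' Write a simulated trial to the CSV formats the pipeline consumes
#'
#' Emits `markers_males.csv`, `markers_females.csv`, `pedigree.csv`,
#' `phenotypes.csv`, `sim_truth_genetic_values.csv` and a YAML echo of the
#' generator configuration.
#'
#' @param sim a `sim_trial`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim_trial <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_markers(sim$males, file.path(dir, "markers_males.csv"))
  write_markers(sim$females, file.path(dir, "markers_females.csv"))
  utils::write.csv(sim$ped, file.path(dir, "pedigree.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$phenos, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  gv <- data.frame(observation = rownames(sim$truth$genetic_value),
                   sim$truth$genetic_value, check.names = FALSE)
  utils::write.csv(gv, file.path(dir, "sim_truth_genetic_values.csv"),
                   row.names = FALSE)
  cfg <- sim$config
  cfg$cor_g <- as.vector(cfg$cor_g); cfg$cor_r <- as.vector(cfg$cor_r)
  yaml::write_yaml(cfg, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
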