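# Deterministic per-stage seed derivation from one master seed.
stage_seed <- function(master, counter) {
  as.integer((as.numeric(master) + 99991 * counter) %% 2147483647)
}

#' Cross-validation plan over hybrids
#'
#' Partitions hybrid ids uniformly at random into `k` near-equal folds
#' (sizes differ by at most 1). All year-records of a hybrid inherit its
#' fold, so a test hybrid is untested in every year ("untested hybrids in
#' tested years").
#'
#' @param hybrids character vector of hybrid ids (no duplicates).
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return data frame of class `cv_plan` with columns `hybrid`, `fold`.
#' @export
make_cv_folds <- function(hybrids, k = 7L, seed = 1L) {
  hybrids <- as.character(hybrids)
  if (anyDuplicated(hybrids)) stop("duplicate hybrid ids")
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be >= 2")
  if (length(hybrids) < k) stop("fewer hybrids than folds")
  set.seed(seed)
  perm <- sample(hybrids)
  fold <- rep(seq_len(k), length.out = length(hybrids))
  out <- data.frame(hybrid = perm, fold = sort(fold),
                    stringsAsFactors = FALSE)
  out <- out[order(out$hybrid), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cv_plan", "data.frame"), k = k, seed = seed)
}

#' Normalized root mean square error
#'
#' `sqrt(mean((obs - pred)^2))` divided by a scale of the observed values:
#' their mean (default, appropriate for strictly positive BLUEs), their SD,
#' or their range.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param normalizer `"mean"`, `"sd"` or `"range"`.
#' @return nonnegative scalar.
#' @export
nrmse <- function(observed, predicted, normalizer = c("mean", "sd", "range")) {
  normalizer <- match.arg(normalizer)
  if (length(observed) != length(predicted) || !length(observed)) {
    stop("'observed' and 'predicted' must have equal positive length")
  }
  rmse <- sqrt(mean((observed - predicted)^2))
  denom <- switch(normalizer,
                  mean = mean(observed),
                  sd = stats::sd(observed),
                  range = diff(range(observed)))
  if (!is.finite(denom) || denom == 0) {
    stop("degenerate normalizer (", normalizer,
         " of observed values is 0); choose another 'normalizer'")
  }
  rmse / abs(denom)
}

#' Relative efficiency of two NRMSE values
#'
#' `RE = nrmse_x / nrmse_ref`: `RE < 1` means method x is the better
#' predictor, `RE = 1` equal efficiency. The companion percentage gain of x
#' over the reference is `(nrmse_ref / nrmse_x - 1) * 100`.
#'
#' @param nrmse_x NRMSE of the candidate method.
#' @param nrmse_ref NRMSE of the reference method.
#' @return list with `re` and `gain_pct`.
#' @export
relative_efficiency <- function(nrmse_x, nrmse_ref) {
  if (any(c(nrmse_x, nrmse_ref) <= 0)) stop("NRMSE values must be positive")
  list(re = nrmse_x / nrmse_ref,
       gain_pct = (nrmse_ref / nrmse_x - 1) * 100)
}

#' Quality-control parental marker panels jointly
#'
#' Stacks male and female panels (same SNP set), applies the missingness
#' filter, naive imputation and MAF filter once on the combined panel, and
#' returns per-sex standardized matrices (for the GCA kernels) plus the
#' combined standardized matrix (for breeding-value estimation across all
#' parents).
#'
#' @param males,females raw `marker_matrix` objects with identical SNP
#'   columns.
#' @param max_missing_frac,min_maf QC thresholds.
#' @return list with `males`, `females`, `parents` (all standardized).
#' @export
prepare_markers <- function(males, females, max_missing_frac = 0.15,
                            min_maf = 0.05) {
  stopifnot(inherits(males, "marker_matrix"),
            inherits(females, "marker_matrix"))
  if (!identical(colnames(males$dosages), colnames(females$dosages))) {
    stop("male and female panels must share the same SNP columns")
  }
  stacked <- marker_matrix(rbind(males$dosages, females$dosages))
  stacked <- filter_maf(impute_naive(
    filter_missingness(stacked, max_missing_frac)), min_maf)
  split_rows <- function(ids) {
    m <- marker_matrix(stacked$dosages[ids, , drop = FALSE], ids = ids,
                       state = "imputed")
    suppressWarnings(standardize_markers(m))
  }
  list(males = split_rows(males$ids),
       females = split_rows(females$ids),
       parents = suppressWarnings(standardize_markers(stacked)))
}

# Abort if any response of a test hybrid is visible to a training fit.
assert_no_leakage <- function(y_visible, obs_hybrids, test_hybrids) {
  test_rows <- obs_hybrids %in% test_hybrids
  if (any(!is.na(y_visible[test_rows, , drop = FALSE]))) {
    stop("test-set leakage: a test hybrid's response is visible in training")
  }
  invisible(TRUE)
}

#' Run the strategy x kernel cross-validation grid
#'
#' For every combination of parental-information strategy (`NO_Cov`,
#' `Pmean`, `BV`) and kernel (`linear`, `GK`, `AC_1` .. `AC_4`), runs the
#' untested-hybrids cross-validation: each fold's test hybrids are masked in
#' all years, the full multi-trait model is fitted to the training
#' responses, and NRMSE is computed per trait within each year over the
#' fold's test observations, then averaged over folds. `Global` is the
#' unweighted mean of the per-year values. Parental covariates are built
#' from parental data only (parents are never masked), so breeding values
#' are estimated once and reused across folds. A leakage guard asserts on
#' every fold that no test-hybrid response enters the training fit.
#'
#' @param data a `sim_trial` or a list with elements `phenos`, `ped`,
#'   `males`, `females` (raw marker panels).
#' @param strategies subset of `c("NO_Cov", "Pmean", "BV")`.
#' @param kernels character kernel names or list of [kernel_spec()]s.
#' @param cv optional `cv_plan`; built from `k` and `seed` when missing.
#' @param k number of folds when `cv` is missing.
#' @param mcmc chain settings for the multi-trait fits
#'   (`list(niter, burnin, thin)`).
#' @param bv_mcmc chain settings for breeding-value estimation.
#' @param seed master seed; per-fit seeds are derived deterministically.
#' @param max_missing_frac,min_maf marker QC thresholds.
#' @param verbose print progress.
#' @return object of class `strategy_grid`: `grid` (fold-averaged NRMSE per
#'   trait x year x strategy x kernel, with `Global` rows), `fold_grid`
#'   (per-fold values), `predictions` (per test observation), `cv`, `seed`,
#'   `failed` (character log of failed fold-fits, if any).
#' @export
run_strategy_grid <- function(data,
                              strategies = c("NO_Cov", "Pmean", "BV"),
                              kernels = "linear",
                              cv = NULL, k = 7L,
                              mcmc = list(niter = 1500L, burnin = 500L,
                                          thin = 2L),
                              bv_mcmc = list(niter = 2000L, burnin = 800L,
                                             thin = 2L),
                              seed = 1L,
                              max_missing_frac = 0.15, min_maf = 0.05,
                              verbose = FALSE) {
  strategies <- match.arg(strategies, c("NO_Cov", "Pmean", "BV"),
                          several.ok = TRUE)
  if (is.character(kernels)) {
    kernels <- lapply(kernels, kernel_spec)
  } else if (inherits(kernels, "kernel_spec")) kernels <- list(kernels)
  kernel_names <- vapply(kernels, function(s) s$name, "")

  phenos <- data$phenos; ped <- data$ped
  design <- build_design(phenos, ped)
  traits <- design$traits
  hybrids <- colnames(design$Z_H)
  if (is.null(cv)) cv <- make_cv_folds(hybrids, k = k, seed = seed)
  extra <- setdiff(cv$hybrid, hybrids)
  if (length(extra)) stop("cv plan contains unknown hybrids")

  prep <- prepare_markers(data$males, data$females, max_missing_frac,
                          min_maf)

  # covariates at the hybrid level (parents never masked -> fold-invariant)
  x_h <- list(NO_Cov = NULL)
  if ("Pmean" %in% strategies) {
    x_h$Pmean <- assemble_covariate_matrix(
      pmean_covariates(phenos, ped, traits))
  }
  if ("BV" %in% strategies) {
    g_par <- ensure_psd(genomic_relationship(prep$parents))
    bvs <- lapply(seq_along(traits), function(j) {
      estimate_breeding_values(phenos, g_par, traits[j],
                               niter = bv_mcmc$niter,
                               burnin = bv_mcmc$burnin,
                               thin = bv_mcmc$thin,
                               seed = stage_seed(seed, 7000L + j))
    })
    names(bvs) <- traits
    x_h$BV <- assemble_covariate_matrix(bv_covariates(bvs, ped, traits))
  }

  fold_rows <- list(); pred_rows <- list(); failed <- character()
  counter <- 0L
  for (ki in seq_along(kernels)) {
    g_m <- ensure_psd(build_kernel(prep$males, kernels[[ki]]))
    g_f <- ensure_psd(build_kernel(prep$females, kernels[[ki]]))
    kl <- model_kernels(design, g_m, g_f)
    eigs <- lapply(kl, kernel_eigen)
    for (f in sort(unique(cv$fold))) {
      test_hy <- cv$hybrid[cv$fold == f]
      mask <- design$mask
      test_rows <- design$obs$hybrid %in% test_hy
      mask[test_rows, ] <- TRUE
      y_visible <- design$Y
      y_visible[mask] <- NA_real_
      assert_no_leakage(y_visible, design$obs$hybrid, test_hy)
      for (st in strategies) {
        counter <- counter + 1L
        x_obs <- if (is.null(x_h[[st]])) NULL else
          x_h[[st]][design$obs$hybrid, , drop = FALSE]
        fit <- tryCatch(
          mtgp(design$Y, kernels = eigs, X = x_obs, mask = mask,
               scalar_terms = "year",
               niter = mcmc$niter, burnin = mcmc$burnin, thin = mcmc$thin,
               seed = stage_seed(seed, counter)),
          error = function(e) e)
        if (inherits(fit, "error")) {
          failed <- c(failed, sprintf("kernel=%s strategy=%s fold=%d: %s",
                                      kernel_names[ki], st, f,
                                      conditionMessage(fit)))
          next
        }
        # test observations with an actually observed response
        eval_rows <- which(test_rows & !apply(design$mask, 1L, all))
        for (j in seq_along(traits)) {
          ok <- eval_rows[!design$mask[eval_rows, j]]
          if (!length(ok)) next
          yr <- design$obs$year[ok]
          for (y in unique(yr)) {
            idx <- ok[yr == y]
            fold_rows[[length(fold_rows) + 1L]] <- data.frame(
              trait = traits[j], year = y, strategy = st,
              kernel = kernel_names[ki], fold = f,
              nrmse = nrmse(design$Y[idx, j], fit$yhat[idx, j]),
              n_test = length(idx), stringsAsFactors = FALSE)
          }
          pred_rows[[length(pred_rows) + 1L]] <- data.frame(
            strategy = st, kernel = kernel_names[ki], fold = f,
            observation = design$obs_ids[ok], trait = traits[j],
            year = design$obs$year[ok],
            observed = design$Y[ok, j], prediction = fit$yhat[ok, j],
            stringsAsFactors = FALSE)
        }
        if (verbose) {
          message(sprintf("kernel %s / strategy %s / fold %d done",
                          kernel_names[ki], st, f))
        }
      }
    }
  }
  fold_grid <- if (length(fold_rows)) do.call(rbind, fold_rows) else
    data.frame(trait = character(), year = character(),
               strategy = character(), kernel = character(),
               fold = integer(), nrmse = numeric(), n_test = integer())
  grid <- aggregate_fold_grid(fold_grid)
  structure(list(grid = grid, fold_grid = fold_grid,
                 predictions = if (length(pred_rows))
                   do.call(rbind, pred_rows) else NULL,
                 cv = cv, seed = seed, mcmc = mcmc, failed = failed,
                 traits = traits, strategies = strategies,
                 kernels = kernel_names),
            class = "strategy_grid")
}

# Fold-average NRMSE per trait x year x strategy x kernel, plus Global rows.
aggregate_fold_grid <- function(fold_grid) {
  if (!nrow(fold_grid)) {
    return(data.frame(trait = character(), year = character(),
                      strategy = character(), kernel = character(),
                      nrmse = numeric()))
  }
  per_year <- stats::aggregate(nrmse ~ trait + year + strategy + kernel,
                               data = fold_grid, FUN = mean)
  glob <- stats::aggregate(nrmse ~ trait + strategy + kernel,
                           data = per_year, FUN = mean)
  glob$year <- "Global"
  out <- rbind(per_year, glob[, names(per_year)])
  out[order(out$trait, out$year, out$strategy, out$kernel), , drop = FALSE]
}

#' @export
print.strategy_grid <- function(x, ...) {
  cat(sprintf("strategy_grid: %s x %s, %d fold(s)\n",
              paste(x$strategies, collapse = "/"),
              paste(x$kernels, collapse = "/"),
              length(unique(x$fold_grid$fold))))
  glob <- x$grid[x$grid$year == "Global", , drop = FALSE]
  if (nrow(glob)) print(glob, row.names = FALSE)
  if (length(x$failed)) {
    cat("failed fits:\n"); cat(paste(" ", x$failed, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Write NRMSE, relative-efficiency and summary tables for a grid run
#'
#' Produces, under `out_dir`: one wide NRMSE table per trait (years as
#' columns, strategy x kernel as rows), a gain table of each strategy
#' against `NO_Cov`, an across-trait mean table, and (optionally) one bar
#' chart per trait of the Global NRMSE by strategy and kernel. Reported
#' tables are rounded to 3 decimals; full precision is kept in the
#' `full_grid.csv` export.
#'
#' @param res a `strategy_grid`.
#' @param out_dir output directory.
#' @param plots write PNG bar charts.
#' @return character vector of files written, invisibly.
#' @export
aggregate_and_report <- function(res, out_dir, plots = TRUE) {
  stopifnot(inherits(res, "strategy_grid"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  if (!nrow(res$grid)) {
    warning("empty results grid; nothing to report")
    utils::write.csv(res$grid, file.path(out_dir, "full_grid.csv"),
                     row.names = FALSE)
    return(invisible(file.path(out_dir, "full_grid.csv")))
  }
  p <- file.path(out_dir, "full_grid.csv")
  utils::write.csv(res$grid, p, row.names = FALSE)
  files <- c(files, p)

  for (tr in unique(res$grid$trait)) {
    sub <- res$grid[res$grid$trait == tr, , drop = FALSE]
    wide <- stats::reshape(sub[, c("year", "strategy", "kernel", "nrmse")],
                           idvar = c("strategy", "kernel"),
                           timevar = "year", direction = "wide")
    names(wide) <- sub("^nrmse\\.", "", names(wide))
    num <- vapply(wide, is.numeric, TRUE)
    wide[num] <- lapply(wide[num], round, 3)
    p <- file.path(out_dir, paste0("nrmse_", tr, ".csv"))
    utils::write.csv(wide, p, row.names = FALSE)
    files <- c(files, p)
  }

  if ("NO_Cov" %in% res$grid$strategy) {
    ref <- res$grid[res$grid$strategy == "NO_Cov",
                    c("trait", "year", "kernel", "nrmse")]
    names(ref)[4] <- "nrmse_ref"
    oth <- res$grid[res$grid$strategy != "NO_Cov", , drop = FALSE]
    gain <- merge(oth, ref, by = c("trait", "year", "kernel"))
    re <- relative_efficiency(gain$nrmse, gain$nrmse_ref)
    gain$re <- round(re$re, 3)
    gain$gain_pct <- round(re$gain_pct, 3)
    gain <- gain[order(gain$trait, gain$year, gain$strategy, gain$kernel), ]
    p <- file.path(out_dir, "re_gain_vs_NO_Cov.csv")
    utils::write.csv(gain, p, row.names = FALSE)
    files <- c(files, p)
  }

  glob <- res$grid[res$grid$year == "Global", , drop = FALSE]
  across <- stats::aggregate(nrmse ~ strategy + kernel, data = glob,
                             FUN = mean)
  across$nrmse <- round(across$nrmse, 3)
  p <- file.path(out_dir, "across_traits_global.csv")
  utils::write.csv(across, p, row.names = FALSE)
  files <- c(files, p)

  if (plots) {
    for (tr in unique(glob$trait)) {
      sub <- glob[glob$trait == tr, , drop = FALSE]
      tab <- stats::xtabs(nrmse ~ strategy + kernel, data = sub)
      p <- file.path(out_dir, paste0("nrmse_global_", tr, ".png"))
      grDevices::png(p, width = 800, height = 500)
      graphics::barplot(tab, beside = TRUE, legend.text = TRUE,
                        main = paste("Global NRMSE,", tr),
                        ylab = "NRMSE", xlab = "kernel")
      grDevices::dev.off()
      files <- c(files, p)
    }
  }
  invisible(files)
}
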