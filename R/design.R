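#' Pedigree tables and phenotype tables
#'
#' The package works with two plain data frames.
#'
#' A *pedigree table* maps each hybrid to its parents; columns `hybrid`,
#' `male`, `female` (character). [pedigree_table()] validates one.
#'
#' A *phenotype table* holds one BLUE per entry x year x trait; columns
#' `entry`, `role` (`"hybrid"`, `"male"` or `"female"`), `year`, then one
#' numeric column per trait (e.g. `GY` in t/ha, `DTF` and `DTH` in days).
#'
#' @param ped data frame with columns `hybrid`, `male`, `female`.
#' @return the validated pedigree data frame.
#' @export
pedigree_table <- function(ped) {
  ped <- as.data.frame(ped)
  need <- c("hybrid", "male", "female")
  if (!all(need %in% names(ped))) {
    stop("pedigree table needs columns: ", paste(need, collapse = ", "))
  }
  ped[need] <- lapply(ped[need], as.character)
  if (anyDuplicated(ped$hybrid)) stop("duplicate hybrid ids in pedigree")
  ped[, need]
}

#' Extract trait column names from a phenotype table
#' @param phenos phenotype data frame.
#' @return character vector of trait names.
#' @export
trait_names <- function(phenos) {
  setdiff(names(phenos), c("entry", "role", "year"))
}

check_phenos <- function(phenos) {
  need <- c("entry", "role", "year")
  if (!all(need %in% names(phenos))) {
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(phenos[, c("entry", "year")])) {
    stop("duplicate (entry, year) rows in phenotype table")
  }
  invisible(phenos)
}

#' Build the observation-level model design
#'
#' Lays out the hybrid records of a phenotype table as the model's
#' observation rows (one row per hybrid x year) and constructs the year,
#' male, female and hybrid incidence matrices, the response matrix `Y`
#' (observations x traits) and a logical mask marking cells to treat as
#' unobserved (used to hold out test hybrids in cross-validation).
#'
#' @param phenos phenotype data frame (see [pedigree_table()] docs).
#' @param ped pedigree data frame.
#' @param mask_hybrids character vector of hybrid ids whose responses are
#'   masked in every year (the "untested hybrids in tested years" scheme).
#' @return a list of class `hybrid_design` with elements `obs` (data frame
#'   of hybrid, male, female, year per observation), `Z_E`, `Z_M`, `Z_F`,
#'   `Z_H`, `Y`, `mask`, `traits`, `years`.
#' @export
build_design <- function(phenos, ped, mask_hybrids = character()) {
  check_phenos(phenos)
  ped <- pedigree_table(ped)
  traits <- trait_names(phenos)
  hy <- phenos[phenos$role == "hybrid", , drop = FALSE]
  if (!nrow(hy)) stop("phenotype table contains no hybrid rows")
  missing_ped <- setdiff(unique(hy$entry), ped$hybrid)
  if (length(missing_ped)) {
    stop("hybrid(s) absent from pedigree: ",
         paste(utils::head(missing_ped, 5L), collapse = ", "),
         if (length(missing_ped) > 5L) ", ...")
  }
  pidx <- match(hy$entry, ped$hybrid)
  obs <- data.frame(hybrid = hy$entry,
                    male = ped$male[pidx],
                    female = ped$female[pidx],
                    year = as.character(hy$year),
                    stringsAsFactors = FALSE)
  obs_ids <- paste(obs$hybrid, obs$year, sep = "@")
  years <- sort(unique(obs$year))
  males <- sort(unique(obs$male))
  females <- sort(unique(obs$female))
  hybrids <- unique(obs$hybrid)

  z_e <- incidence_matrix(obs$year, years, obs_ids)
  z_m <- incidence_matrix(obs$male, males, obs_ids)
  z_f <- incidence_matrix(obs$female, females, obs_ids)
  z_h <- incidence_matrix(obs$hybrid, hybrids, obs_ids)

  y <- as.matrix(hy[, traits, drop = FALSE])
  rownames(y) <- obs_ids
  mask <- is.na(y)
  if (length(mask_hybrids)) {
    unknown <- setdiff(mask_hybrids, hybrids)
    if (length(unknown)) {
      stop("mask_hybrids not present in the data: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
    mask[obs$hybrid %in% mask_hybrids, ] <- TRUE
  }
  structure(list(obs = obs, obs_ids = obs_ids,
                 Z_E = z_e, Z_M = z_m, Z_F = z_f, Z_H = z_h,
                 Y = y, mask = mask, traits = traits, years = years),
            class = "hybrid_design")
}

#' @export
print.hybrid_design <- function(x, ...) {
  cat(sprintf(paste0("hybrid_design: %d observations (%d hybrids, %d males, ",
                     "%d females, %d years), %d trait(s), %d masked cell(s)\n"),
              nrow(x$Y), ncol(x$Z_H), ncol(x$Z_M), ncol(x$Z_F),
              ncol(x$Z_E), ncol(x$Y), sum(x$mask)))
  invisible(x)
}

#' Observation-level kernels for the full hybrid model
#'
#' Builds the seven structured terms of the multi-trait hybrid model from a
#' design and the parental relationship matrices: the year block kernel, the
#' male and female GCA kernels `Z G Z'`, the SCA kernel from the hybrid-level
#' Hadamard product, and the three kernel-by-year interaction kernels that
#' mask each of them by year co-membership.
#'
#' @param design a `hybrid_design`.
#' @param g_m,g_f parental `kernel_matrix` objects (any of the six kernels).
#' @return named list of observation-level `kernel_matrix` objects:
#'   `year`, `gca_m`, `gca_f`, `sca`, `gca_m_year`, `gca_f_year`, `sca_year`.
#' @export
model_kernels <- function(design, g_m, g_f) {
  stopifnot(inherits(design, "hybrid_design"))
  # hybrid-level incidence of parents (one row per distinct hybrid)
  hid <- colnames(design$Z_H)
  first <- match(hid, design$obs$hybrid)
  zm_h <- incidence_matrix(design$obs$male[first], colnames(design$Z_M), hid)
  zf_h <- incidence_matrix(design$obs$female[first], colnames(design$Z_F), hid)
  h <- hybrid_kernel(zm_h, g_m, zf_h, g_f)

  k_year <- kernel_matrix(tcrossprod(design$Z_E), ids = design$obs_ids,
                          kind = "hadamard")
  k_gm <- expand_kernel(design$Z_M, g_m)
  k_gf <- expand_kernel(design$Z_F, g_f)
  k_sca <- expand_kernel(design$Z_H, h)
  list(year = k_year,
       gca_m = k_gm,
       gca_f = k_gf,
       sca = k_sca,
       gca_m_year = interaction_kernel(k_gm, design$Z_E),
       gca_f_year = interaction_kernel(k_gf, design$Z_E),
       sca_year = interaction_kernel(k_sca, design$Z_E))
}
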