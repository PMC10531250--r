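#' Marker dosage matrices
#'
#' A `marker_matrix` holds an individuals-by-SNP allele dosage table together
#' with a missingness mask and a processing state. Dosages count copies of the
#' counted allele (0, 1 or 2); inbred wheat parents are mostly 0/2 but
#' heterozygous calls are accepted. The state moves monotonically through
#' `"raw"` (may contain missing cells), `"imputed"` (missing cells replaced by
#' the column mean, i.e. twice the observed allele frequency) and
#' `"standardized"` (columns centered and scaled to unit population SD, ready
#' for kernel construction).
#'
#' @param dosages numeric matrix, individuals in rows, SNPs in columns.
#'   `NA` cells are treated as missing.
#' @param ids character vector of individual identifiers; defaults to the
#'   rownames of `dosages`.
#' @param state processing state, one of `"raw"`, `"imputed"`,
#'   `"standardized"`.
#' @return an object of class `marker_matrix`.
#' @export
marker_matrix <- function(dosages, ids = rownames(dosages), state = "raw") {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(dosages)))
  ids <- as.character(ids)
  if (length(ids) != nrow(dosages)) {
    stop("length of 'ids' must equal the number of rows of 'dosages'")
  }
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  state <- match.arg(state, c("raw", "imputed", "standardized"))
  if (state == "raw") {
    # imputed matrices may carry continuous column-mean values
    vals <- dosages[!is.na(dosages)]
    if (length(vals) && !all(vals %in% c(0, 1, 2))) {
      stop("non-missing dosages must be 0, 1 or 2 in a raw marker matrix")
    }
  }
  if (state != "raw" && anyNA(dosages)) {
    stop("state '", state, "' cannot contain missing dosages")
  }
  rownames(dosages) <- ids
  if (is.null(colnames(dosages)) && ncol(dosages) > 0L) {
    colnames(dosages) <- paste0("snp", seq_len(ncol(dosages)))
  }
  structure(list(ids = ids, dosages = dosages, state = state),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat(sprintf("marker_matrix: %d individuals x %d SNPs [%s, %.1f%% missing]\n",
              nrow(x$dosages), ncol(x$dosages), x$state, 100 * miss))
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$dosages)

#' Read a marker dosage CSV
#'
#' Expects a header row of SNP names and a first column of individual ids;
#' cells are 0/1/2 or empty/`NA` for missing. Set `transposed = TRUE` when
#' the file stores SNPs in rows and individuals in columns.
#'
#' @param path CSV file path.
#' @param transposed logical; file is SNPs-by-individuals.
#' @return a `marker_matrix` in state `"raw"`.
#' @export
read_markers <- function(path, transposed = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (transposed) m <- t(m)
  marker_matrix(m, state = "raw")
}

#' Write a marker matrix to CSV
#' @param m a `marker_matrix`.
#' @param path output file path.
#' @export
write_markers <- function(m, path) {
  stopifnot(inherits(m, "marker_matrix"))
  df <- data.frame(id = m$ids, m$dosages, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Drop SNPs with too many missing calls
#'
#' Retains columns whose missing fraction is strictly below
#' `max_missing_frac` (the default mirrors the common "less than 15% missing"
#' rule for genotyping-array panels).
#'
#' @param m a raw `marker_matrix`.
#' @param max_missing_frac maximum tolerated missing fraction in `[0, 1]`.
#' @return filtered `marker_matrix`, column order preserved.
#' @export
filter_missingness <- function(m, max_missing_frac = 0.15) {
  stopifnot(inherits(m, "marker_matrix"))
  if (m$state != "raw") stop("filter_missingness expects a raw marker_matrix")
  if (max_missing_frac < 0 || max_missing_frac > 1) {
    stop("'max_missing_frac' must lie in [0, 1]")
  }
  frac <- colMeans(is.na(m$dosages))
  keep <- frac < max_missing_frac
  if (!any(keep)) {
    stop("all SNPs removed by the missingness filter; empty marker panel")
  }
  marker_matrix(m$dosages[, keep, drop = FALSE], ids = m$ids, state = "raw")
}

#' Naive mean imputation of missing dosages
#'
#' Each missing cell is replaced by the mean of the observed dosages in its
#' column, i.e. twice the observed allele frequency. Values are left
#' continuous; downstream kernel construction does not need integer dosages.
#'
#' @param m a raw `marker_matrix`.
#' @return `marker_matrix` with state `"imputed"`.
#' @export
impute_naive <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  if (m$state != "raw") stop("impute_naive expects a raw marker_matrix")
  d <- m$dosages
  n_obs <- colSums(!is.na(d))
  if (any(n_obs == 0L)) {
    stop("SNP(s) with no observed dosages cannot be imputed: ",
         paste(colnames(d)[n_obs == 0L], collapse = ", "))
  }
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- mu[idx[, 2L]]
  marker_matrix(d, ids = m$ids, state = "imputed")
}

#' Minor allele frequency filter
#'
#' The allele frequency of a column is its mean dosage divided by 2; the MAF
#' is `min(f, 1 - f)`. Columns with MAF strictly below `min_maf` are removed.
#'
#' @param m an imputed `marker_matrix`.
#' @param min_maf minimum minor allele frequency in `[0, 0.5]`.
#' @return filtered `marker_matrix`.
#' @export
filter_maf <- function(m, min_maf = 0.05) {
  stopifnot(inherits(m, "marker_matrix"))
  if (m$state != "imputed") stop("filter_maf expects an imputed marker_matrix")
  if (min_maf < 0 || min_maf > 0.5) stop("'min_maf' must lie in [0, 0.5]")
  f <- colMeans(m$dosages) / 2
  maf <- pmin(f, 1 - f)
  keep <- maf >= min_maf
  if (!any(keep)) warning("MAF filter removed every SNP")
  marker_matrix(m$dosages[, keep, drop = FALSE], ids = m$ids,
                state = "imputed")
}

#' Center and scale marker columns
#'
#' Columns are centered and divided by their population standard deviation
#' (divisor `n`), so that the linear genomic relationship matrix built from
#' the result has mean diagonal exactly 1. Zero-variance (monomorphic)
#' columns are dropped with a warning.
#'
#' @param m an imputed `marker_matrix`.
#' @return `marker_matrix` with state `"standardized"`.
#' @export
standardize_markers <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  if (m$state != "imputed") {
    stop("standardize_markers expects an imputed marker_matrix")
  }
  d <- m$dosages
  n <- nrow(d)
  mu <- colMeans(d)
  sd_pop <- sqrt(colMeans(d^2) - mu^2)
  keep <- sd_pop > 1e-12
  if (!all(keep)) {
    warning(sum(!keep), " monomorphic SNP(s) dropped during standardization")
  }
  d <- sweep(d[, keep, drop = FALSE], 2L, mu[keep], "-")
  d <- sweep(d, 2L, sd_pop[keep], "/")
  marker_matrix(d, ids = m$ids, state = "standardized")
}

#' Run the full marker quality-control chain
#'
#' Convenience wrapper: missingness filter, naive imputation, MAF filter,
#' standardization.
#'
#' @inheritParams filter_missingness
#' @inheritParams filter_maf
#' @return a standardized `marker_matrix`.
#' @export
qc_markers <- function(m, max_missing_frac = 0.15, min_maf = 0.05) {
  standardize_markers(filter_maf(impute_naive(
    filter_missingness(m, max_missing_frac)), min_maf))
}

#' Linear (VanRaden) genomic relationship matrix
#'
#' Computes `G = W W' / p` from a standardized marker matrix `W` with `p`
#' SNPs. With population-SD standardization the mean diagonal of `G` is
#' exactly 1.
#'
#' @param w a standardized `marker_matrix`.
#' @return a [kernel_matrix] of kind `"linear"`.
#' @export
genomic_relationship <- function(w) {
  stopifnot(inherits(w, "marker_matrix"))
  if (w$state != "standardized") {
    stop("genomic_relationship expects a standardized marker_matrix")
  }
  p <- ncol(w$dosages)
  if (p < 1L) stop("at least one SNP is required")
  g <- tcrossprod(w$dosages) / p
  g <- (g + t(g)) / 2
  kernel_matrix(g, ids = w$ids, kind = "linear")
}
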