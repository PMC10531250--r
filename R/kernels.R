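#' Kernel (relationship) matrices
#'
#' A `kernel_matrix` is a symmetric positive semi-definite similarity matrix
#' with row/column identifiers: the linear genomic relationship matrix, a
#' Gaussian kernel, an arc-cosine kernel, or an observation-level composite
#' built by incidence expansion and Hadamard products.
#'
#' @param values symmetric numeric matrix.
#' @param ids identifiers for the rows/columns.
#' @param kind label: `"linear"`, `"GK"`, `"AC_l"` or `"hadamard"`.
#' @return an object of class `kernel_matrix`.
#' @export
kernel_matrix <- function(values, ids = rownames(values), kind = "linear") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("kernel matrix must be square")
  if (max(abs(values - t(values))) > 1e-10) {
    stop("kernel matrix must be symmetric (within 1e-10)")
  }
  if (is.null(ids)) ids <- paste0("id", seq_len(nrow(values)))
  ids <- as.character(ids)
  if (length(ids) != nrow(values)) stop("ids length must match dimension")
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values, kind = kind),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix [%s]: %d x %d, mean diag %.4f\n",
              x$kind, nrow(x$values), ncol(x$values),
              mean(diag(x$values))))
  invisible(x)
}

#' @export
dim.kernel_matrix <- function(x) dim(x$values)

#' Write a kernel matrix to CSV (ids as header and first column)
#' @param k a `kernel_matrix`.
#' @param path output file path.
#' @export
write_kernel <- function(k, path) {
  stopifnot(inherits(k, "kernel_matrix"))
  df <- data.frame(id = k$ids, k$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a kernel matrix written by [write_kernel()]
#' @param path CSV file path.
#' @param kind kernel kind label to attach.
#' @export
read_kernel <- function(path, kind = "linear") {
  df <- utils::read.csv(path, check.names = FALSE)
  v <- as.matrix(df[, -1L, drop = FALSE])
  rownames(v) <- as.character(df[[1L]])
  # CSV round-trips can leave asymmetry at the last printed digit
  v <- (v + t(v)) / 2
  kernel_matrix(v, ids = rownames(v), kind = kind)
}

#' Kernel specification
#'
#' Names one of the six candidate parental kernels: `linear` (GBLUP),
#' `GK` (Gaussian kernel with bandwidth `gamma` on the mean-scaled squared
#' distance axis), or `AC_1` .. `AC_4` (arc-cosine kernels with 1-4 hidden
#' layers and activation `degree`, default 1 = ramp).
#'
#' @param name kernel name.
#' @param gamma positive Gaussian bandwidth (GK only).
#' @param layers number of arc-cosine layers (AC only, 1-4 by convention).
#' @param degree arc-cosine activation degree (>= 0).
#' @export
kernel_spec <- function(name = c("linear", "GK", "AC_1", "AC_2", "AC_3", "AC_4"),
                        gamma = 1, layers = NULL, degree = 1L) {
  name <- match.arg(name)
  if (grepl("^AC_", name)) {
    layers <- as.integer(sub("AC_", "", name))
  } else if (is.null(layers)) layers <- 1L
  if (!is.null(gamma) && gamma <= 0) stop("'gamma' must be positive")
  structure(list(name = name, gamma = gamma, layers = as.integer(layers),
                 degree = as.integer(degree)),
            class = "kernel_spec")
}

#' Build a parental kernel from standardized markers
#'
#' Dispatches on a [kernel_spec()]: the linear VanRaden relationship matrix,
#' the Gaussian kernel, or the arc-cosine kernel with the requested depth.
#'
#' @param w standardized `marker_matrix`.
#' @param spec a [kernel_spec()] or kernel name string.
#' @return a `kernel_matrix`.
#' @export
build_kernel <- function(w, spec = kernel_spec("linear")) {
  if (is.character(spec)) spec <- kernel_spec(spec)
  switch(sub("_[0-9]+$", "", spec$name),
         linear = genomic_relationship(w),
         GK = gaussian_kernel(w, gamma = spec$gamma),
         AC = arc_cosine_kernel(w, layers = spec$layers, degree = spec$degree),
         stop("unknown kernel: ", spec$name))
}

#' Gaussian (radial basis function) kernel
#'
#' `K[i, j] = exp(-gamma * d2[i, j] / mean(d2))` where `d2` is the squared
#' Euclidean distance between marker rows and `mean(d2)` averages the
#' off-diagonal pairs. Scaling distances by their mean makes `gamma = 1` a
#' sensible default bandwidth regardless of marker count. The diagonal is
#' exactly 1.
#'
#' @param w standardized `marker_matrix`.
#' @param gamma positive bandwidth.
#' @return a `kernel_matrix` of kind `"GK"`.
#' @export
gaussian_kernel <- function(w, gamma = 1) {
  stopifnot(inherits(w, "marker_matrix"))
  if (w$state != "standardized") {
    stop("gaussian_kernel expects a standardized marker_matrix")
  }
  if (gamma <= 0) stop("'gamma' must be positive")
  x <- w$dosages
  n <- nrow(x)
  if (n == 1L) return(kernel_matrix(matrix(1, 1, 1), ids = w$ids, kind = "GK"))
  d2 <- as.matrix(stats::dist(x))^2
  md <- mean(d2[upper.tri(d2)])
  if (md <= 0) {
    warning("all marker rows identical; Gaussian kernel is a matrix of ones")
    k <- matrix(1, n, n)
  } else {
    k <- exp(-gamma * d2 / md)
  }
  diag(k) <- 1
  kernel_matrix((k + t(k)) / 2, ids = w$ids, kind = "GK")
}

# Degree-n arc-cosine angular factor J_n(theta).
# J_0 = pi - theta; J_1 = sin(theta) + (pi - theta) cos(theta);
# J_2 = 3 sin(theta) cos(theta) + (pi - theta)(1 + 2 cos^2(theta)).
ac_angular <- function(theta, degree) {
  switch(as.character(degree),
         "0" = pi - theta,
         "1" = sin(theta) + (pi - theta) * cos(theta),
         "2" = 3 * sin(theta) * cos(theta) +
           (pi - theta) * (1 + 2 * cos(theta)^2),
         stop("arc-cosine degree must be 0, 1 or 2"))
}

#' Arc-cosine (deep neural network) kernel
#'
#' The Cho-Saul kernel of an infinite-width network with `layers` hidden
#' layers and activation degree `degree` (1 = ramp). The base layer is
#' `k(x, y) = (1/pi) * (|x| |y|)^n * J_n(theta)` with
#' `theta = arccos(x . y / (|x| |y|))`; deeper layers apply
#' `k^(l+1)(x, y) = (1/pi) * [k^(l)(x,x) k^(l)(y,y)]^(n/2) * J_n(theta^(l))`
#' where `theta^(l)` comes from the layer-`l` kernel normalized to unit
#' diagonal. The returned matrix is rescaled by its mean diagonal so that
#' `mean(diag(K)) = 1`, keeping variance priors comparable with the linear
#' and Gaussian kernels. Cosines are clamped to `[-1, 1]` before `acos`.
#'
#' @param w standardized `marker_matrix`.
#' @param layers integer >= 1, number of hidden layers.
#' @param degree activation degree (0, 1 or 2).
#' @return a `kernel_matrix` of kind `"AC_<layers>"`.
#' @export
arc_cosine_kernel <- function(w, layers = 1L, degree = 1L) {
  stopifnot(inherits(w, "marker_matrix"))
  if (w$state != "standardized") {
    stop("arc_cosine_kernel expects a standardized marker_matrix")
  }
  layers <- as.integer(layers)
  if (layers < 1L) stop("'layers' must be >= 1")
  x <- w$dosages
  nrm2 <- rowSums(x^2)
  if (any(nrm2 <= 0)) {
    stop("zero-norm marker row(s): ",
         paste(w$ids[nrm2 <= 0], collapse = ", "))
  }
  ip <- tcrossprod(x)
  k <- ac_layer(ip, degree)
  if (layers > 1L) {
    for (l in seq_len(layers - 1L)) k <- ac_layer(k, degree)
  }
  k <- k / mean(diag(k))
  kernel_matrix((k + t(k)) / 2, ids = w$ids, kind = paste0("AC_", layers))
}

# One arc-cosine layer applied to an inner-product (or kernel) matrix.
ac_layer <- function(ip, degree) {
  dg <- diag(ip)
  denom <- sqrt(outer(dg, dg))
  cth <- pmin(pmax(ip / denom, -1), 1)
  theta <- acos(cth)
  (1 / pi) * denom^degree * ac_angular(theta, degree)
}

#' Incidence matrices
#'
#' A 0/1 matrix with one row per observation and one column per factor level
#' (year, male, female or hybrid), exactly one 1 per row.
#'
#' @param levels_per_obs character/factor vector giving the level of each
#'   observation.
#' @param levels optional complete level set (defaults to observed levels).
#' @param obs_ids optional observation identifiers.
#' @return 0/1 matrix with observation rownames and level colnames.
#' @export
incidence_matrix <- function(levels_per_obs, levels = NULL, obs_ids = NULL) {
  levels_per_obs <- as.character(levels_per_obs)
  if (is.null(levels)) levels <- unique(levels_per_obs)
  bad <- setdiff(levels_per_obs, levels)
  if (length(bad)) {
    stop("observation mapped to unknown level(s): ",
         paste(unique(bad), collapse = ", "))
  }
  n <- length(levels_per_obs)
  z <- matrix(0, n, length(levels), dimnames = list(obs_ids, levels))
  z[cbind(seq_len(n), match(levels_per_obs, levels))] <- 1
  z
}

#' Expand a level kernel to observation level
#'
#' Computes `Z K Z'` so that entry `(o, o')` equals the kernel value between
#' the levels of observations `o` and `o'`.
#'
#' @param z incidence matrix (observations x levels).
#' @param k `kernel_matrix` over the levels.
#' @return observation-level `kernel_matrix`.
#' @export
expand_kernel <- function(z, k) {
  stopifnot(inherits(k, "kernel_matrix"))
  lev <- colnames(z)
  if (is.null(lev)) stop("incidence matrix must have level colnames")
  miss <- setdiff(lev, k$ids)
  if (length(miss)) {
    stop("incidence levels missing from kernel: ",
         paste(miss, collapse = ", "))
  }
  kv <- k$values[lev, lev, drop = FALSE]
  v <- z %*% kv %*% t(z)
  ids <- rownames(z)
  if (is.null(ids)) ids <- paste0("obs", seq_len(nrow(z)))
  kernel_matrix((v + t(v)) / 2, ids = ids, kind = "hadamard")
}

#' Hybrid (specific combining ability) kernel
#'
#' `H = (Z_M G_M Z_M') o (Z_F G_F Z_F')` at the hybrid level: the Hadamard
#' product of the male and female relationship matrices expanded over the
#' hybrid list. PSD by the Schur product theorem.
#'
#' @param z_m,z_f incidence matrices mapping the same hybrid list to male
#'   and female parents.
#' @param g_m,g_f parental `kernel_matrix` objects.
#' @return hybrid-level `kernel_matrix`.
#' @export
hybrid_kernel <- function(z_m, g_m, z_f, g_f) {
  if (nrow(z_m) != nrow(z_f) ||
      !identical(rownames(z_m), rownames(z_f))) {
    stop("male and female incidence matrices must index the same hybrids")
  }
  km <- expand_kernel(z_m, g_m)
  kf <- expand_kernel(z_f, g_f)
  kernel_matrix(km$values * kf$values, ids = km$ids, kind = "hadamard")
}

#' Kernel-by-year interaction kernel
#'
#' Masks an observation-level kernel by year co-membership:
#' `V = K o (Z_E Z_E')`, keeping similarity within a year and zeroing it
#' across years.
#'
#' @param expanded observation-level `kernel_matrix`.
#' @param z_e year incidence matrix with the same row order.
#' @return observation-level `kernel_matrix`.
#' @export
interaction_kernel <- function(expanded, z_e) {
  stopifnot(inherits(expanded, "kernel_matrix"))
  if (nrow(z_e) != nrow(expanded$values)) {
    stop("incidence matrix and kernel have different numbers of observations")
  }
  same_year <- tcrossprod(z_e)
  kernel_matrix(expanded$values * same_year, ids = expanded$ids,
                kind = "hadamard")
}

#' Guarantee positive semi-definiteness by diagonal jitter
#'
#' If the minimum eigenvalue is below `-1e-8`, adds `jitter * I`, escalating
#' the jitter tenfold (up to 6 times) until the matrix is PSD; the amount
#' added is reported via a message.
#'
#' @param k `kernel_matrix`.
#' @param jitter starting jitter.
#' @return PSD `kernel_matrix`.
#' @export
ensure_psd <- function(k, jitter = 1e-8) {
  stopifnot(inherits(k, "kernel_matrix"))
  v <- k$values
  min_eig <- min(eigen(v, symmetric = TRUE, only.values = TRUE)$values)
  if (min_eig >= -1e-8) return(k)
  added <- 0
  j <- jitter
  for (i in seq_len(6L)) {
    need <- -min_eig + j
    v <- v + diag(need, nrow(v))
    added <- added + need
    min_eig <- min(eigen(v, symmetric = TRUE, only.values = TRUE)$values)
    if (min_eig >= -1e-8) {
      message(sprintf("ensure_psd: added %.3g to the diagonal", added))
      k$values <- v
      return(k)
    }
    j <- j * 10
  }
  stop("matrix still indefinite after 6 jitter escalations")
}
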