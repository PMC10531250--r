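# Fixtures are generated in code; nothing is read from disk.

# Small raw marker matrix with a known missingness pattern.
tiny_markers <- function() {
  d <- matrix(c(0, 2, NA, 2,    # 25% missing
                0, 1, 1, 2,     # complete, MAF 0.5
                2, 2, 2, 2,     # monomorphic
                0, 0, 2, NA),   # 25% missing
              nrow = 4, dimnames = list(paste0("i", 1:4),
                                        paste0("s", 1:4)))
  marker_matrix(d)
}

# Random standardized marker matrix (bypasses QC for kernel tests).
random_std_markers <- function(n, p, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p)
  x <- scale(x)
  x <- sweep(x, 2, sqrt(colMeans(x^2)), "/")   # population SD 1
  marker_matrix(x, ids = sprintf("ind%02d", seq_len(n)),
                state = "standardized")
}

# Random PSD matrix with unit-scale diagonal.
random_psd <- function(n, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * (n + 2)), n)
  v <- tcrossprod(x) / (n + 2)
  kernel_matrix(v, ids = paste0("l", seq_len(n)))
}

# Desk-size simulated trial shared by several tests.
tiny_trial <- function(seed = 3, ...) {
  cfg <- sim_config(n_males = 6, n_females = 24, crosses_per_female = 2,
                    n_markers = 120, n_years = 2, ...)
  simulate_hybrid_trial(cfg, seed = seed)
}
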