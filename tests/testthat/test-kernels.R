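test_that("Gaussian kernel follows the mean-scaled distance formula", {
  # 1-D rows at 0, sqrt(2), 2*sqrt(2): pairwise d^2 = {2, 2, 8}, mean 4
  w <- marker_matrix(matrix(c(0, sqrt(2), 2 * sqrt(2))),
                     ids = c("a", "b", "c"), state = "standardized")
  k <- gaussian_kernel(w, gamma = 1)
  expect_equal(k$values["a", "b"], exp(-2 / 4))
  expect_equal(k$values["b", "c"], exp(-2 / 4))
  expect_equal(k$values["a", "c"], exp(-8 / 4))
  expect_equal(diag(k$values), c(a = 1, b = 1, c = 1))

  # gamma -> 0 limit is the all-ones matrix
  k0 <- gaussian_kernel(w, gamma = 1e-12)
  expect_equal(unname(k0$values), matrix(1, 3, 3), tolerance = 1e-9)

  # identical rows give kernel value 1
  w2 <- marker_matrix(rbind(c(1, -1), c(1, -1), c(0, 1)),
                      state = "standardized")
  expect_equal(gaussian_kernel(w2, 2)$values[1, 2], 1)
})

test_that("Gaussian kernel is equivariant to relabeling individuals", {
  w <- random_std_markers(7, 30, seed = 9)
  k <- gaussian_kernel(w, 1.5)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  wp <- marker_matrix(w$dosages[perm, ], ids = w$ids[perm],
                      state = "standardized")
  kp <- gaussian_kernel(wp, 1.5)
  expect_equal(kp$values, k$values[perm, perm])
})

test_that("arc-cosine kernel reproduces the degree-1 closed form", {
  # identical unit-norm rows: J1(0) = pi so k(x,x) = |x|^2 -> normalized 1
  u <- c(1, 0) / 1
  w_id <- marker_matrix(rbind(u, u), ids = c("a", "b"),
                        state = "standardized")
  for (l in 1:4) {
    k <- arc_cosine_kernel(w_id, layers = l)
    expect_equal(k$values["a", "b"], 1, tolerance = 1e-12)
  }
  # orthogonal unit rows, 1 layer: J1(pi/2) = 1 -> k = 1/pi (diag rescale
  # is a no-op because k(x,x) = 1)
  w_o <- marker_matrix(rbind(c(1, 0), c(0, 1)), state = "standardized")
  expect_equal(arc_cosine_kernel(w_o, 1)$values[1, 2], 1 / pi)
  # antiparallel unit rows: J1(pi) = 0
  w_a <- marker_matrix(rbind(c(1, 0), c(-1, 0)), state = "standardized")
  expect_equal(arc_cosine_kernel(w_a, 1)$values[1, 2], 0)
  # zero-norm row is refused by name
  w_z <- marker_matrix(rbind(c(0, 0), c(1, 0)), ids = c("bad", "ok"),
                       state = "standardized")
  expect_error(arc_cosine_kernel(w_z, 1), "bad")
})

test_that("all six kernels share mean diagonal 1 on the same individuals", {
  w <- random_std_markers(10, 60, seed = 5)
  specs <- c("linear", "GK", "AC_1", "AC_2", "AC_3", "AC_4")
  for (s in specs) {
    k <- build_kernel(w, kernel_spec(s))
    expect_equal(mean(diag(k$values)), 1, tolerance = 1e-8,
                 label = paste("mean diag of", s))
    expect_gte(min(eigen(k$values, TRUE, TRUE)$values), -1e-8)
  }
})

test_that("incidence expansion equals per-entry kernel lookup", {
  k <- random_psd(3, seed = 11)
  set.seed(12)
  lv <- sample(k$ids, 9, replace = TRUE)
  z <- incidence_matrix(lv, k$ids, paste0("o", 1:9))
  ek <- expand_kernel(z, k)
  # brute-force elementwise oracle
  for (i in 1:9) for (j in 1:9) {
    expect_equal(ek$values[i, j], k$values[lv[i], lv[j]])
  }
  # identity kernel -> same-level indicator
  id <- kernel_matrix(diag(3), ids = k$ids)
  ei <- expand_kernel(z, id)
  expect_equal(unname(ei$values), outer(lv, lv, "==") + 0)
  expect_error(expand_kernel(incidence_matrix("x", "x"), k),
               "missing from kernel")
})

test_that("hybrid SCA kernel is the Hadamard product of expanded parent kernels", {
  gm <- random_psd(3, seed = 21); gf <- random_psd(4, seed = 22)
  hyb <- c("h1", "h2", "h3", "h4", "h5")
  zm <- incidence_matrix(c("l1", "l1", "l2", "l3", "l2"), gm$ids, hyb)
  zf <- incidence_matrix(c("l1", "l2", "l3", "l4", "l3"), gf$ids, hyb)
  h <- hybrid_kernel(zm, gm, zf, gf)
  oracle <- (zm %*% gm$values %*% t(zm)) * (zf %*% gf$values %*% t(zf))
  expect_equal(h$values, oracle, ignore_attr = TRUE)

  # identity parent kernels: shared male, different females -> 0
  im <- kernel_matrix(diag(3), ids = gm$ids)
  iff <- kernel_matrix(diag(4), ids = gf$ids)
  h0 <- hybrid_kernel(zm, im, zf, iff)
  expect_equal(h0$values["h1", "h2"], 0)   # same male l1, females l1 vs l2
  # same cross repeated -> product of parental self-similarities
  expect_equal(h$values["h3", "h5"],
               gm$values["l2", "l2"] * gf$values["l3", "l3"])
  expect_error(hybrid_kernel(zm[1:3, ], gm, zf, gf), "same hybrids")
})

test_that("year-interaction kernel zeroes similarity across years", {
  k <- random_psd(6, seed = 31)
  yr <- c("1", "1", "2", "2", "3", "3")
  z_e <- incidence_matrix(yr, c("1", "2", "3"), k$ids)
  v <- interaction_kernel(k, z_e)
  expect_equal(v$values, k$values * outer(yr, yr, "=="), ignore_attr = TRUE)
  # one year only: masking is a no-op
  z1 <- incidence_matrix(rep("1", 6), "1", k$ids)
  expect_equal(interaction_kernel(k, z1)$values, k$values)
  expect_error(interaction_kernel(k, z_e[1:3, , drop = FALSE]),
               "different numbers")
})

test_that("Hadamard products of PSD kernels stay PSD", {
  for (s in 1:40) {
    a <- random_psd(5, seed = 1000 + s)
    b <- random_psd(5, seed = 2000 + s)
    had <- a$values * b$values
    expect_gte(min(eigen(had, TRUE, TRUE)$values), -1e-8)
  }
})

test_that("ensure_psd repairs indefinite matrices and passes PSD through", {
  ind <- kernel_matrix(matrix(c(1, 1.2, 1.2, 1), 2))  # eigenvalues -0.2, 2.2
  expect_message(fixed <- ensure_psd(ind), "added")
  expect_gte(min(eigen(fixed$values, TRUE, TRUE)$values), -1e-8)
  id <- kernel_matrix(diag(3))
  expect_identical(ensure_psd(id)$values, id$values)
  g <- random_psd(6, seed = 41)
  expect_identical(ensure_psd(g)$values, g$values)
})

test_that("kernel CSV round-trip preserves ids and values", {
  k <- random_psd(4, seed = 51)
  p <- tempfile(fileext = ".csv")
  write_kernel(k, p)
  back <- read_kernel(p)
  expect_equal(back$values, k$values, tolerance = 1e-12)
  expect_identical(back$ids, k$ids)
})
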