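test_that("GNM of a 3-bead path reproduces the path-Laplacian spectrum", {
  tr <- toy_trace(cbind(c(0, 4, 8), 0, 0))
  g <- build_gnm(tr, cutoff = 7.3)
  expect_equal(g$eigenvalues, c(1, 3), tolerance = 1e-10)
  expect_equal(g$n_zero, 1L)
  expect_equal(g$n_modes, 2L)
})

test_that("GNM of a triangle gives the degenerate complete-graph spectrum", {
  tr <- toy_trace(cbind(c(0, 4, 2), c(0, 0, 3.5), 0))
  expect_warning(g <- build_gnm(tr, cutoff = 7.3), "degenerate")
  expect_equal(g$eigenvalues, c(3, 3), tolerance = 1e-10)
})

test_that("GNM eigenvalues match the closed-form path-graph spectrum for n <= 6", {
  # independent oracle: path Laplacian eigenvalues are 4 sin^2(k pi / 2n)
  for (n in 4:6) {
    tr <- toy_trace(cbind(seq(0, by = 4, length.out = n), 0, 0))
    g <- build_gnm(tr, cutoff = 7.3)
    expected <- sort(4 * sin(seq_len(n - 1) * pi / (2 * n))^2)
    expect_equal(g$eigenvalues, expected, tolerance = 1e-8)
  }
})

test_that("Kirchhoff rows sum to zero and the Hessian annihilates rigid motions", {
  tr <- toy_cloud(12)
  K <- kirchhoff_matrix(tr, 7.3)
  expect_equal(max(abs(rowSums(K))), 0, tolerance = 1e-12)

  coords <- trace_coords(tr)
  H <- anm_hessian(coords, 13)
  centered <- sweep(coords, 2, colMeans(coords))
  rigid <- cbind(
    rep(c(1, 0, 0), nrow(coords)),
    rep(c(0, 1, 0), nrow(coords)),
    rep(c(0, 0, 1), nrow(coords)),
    as.vector(t(cbind(0, -centered[, 3], centered[, 2]))),
    as.vector(t(cbind(centered[, 3], 0, -centered[, 1]))),
    as.vector(t(cbind(-centered[, 2], centered[, 1], 0)))
  )
  expect_lt(max(abs(H %*% rigid)), 1e-8)
})

test_that("ANM zero-mode bookkeeping: tetrahedron has 6 + 6 modes", {
  tr <- toy_trace(3.5 * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                              c(-1, -1, 1)))
  a <- suppressWarnings(build_anm(tr, cutoff = 13))
  expect_equal(a$n_zero, 6L)
  expect_equal(a$n_modes, 6L)
  expect_true(all(a$eigenvalues > 1e-8))
})

test_that("eigenvectors are orthonormal and satisfy the eigen equation", {
  tr <- toy_cloud(14, seed = 21)
  g <- build_gnm(tr, 7.3)
  G <- crossprod(g$eigenvectors)
  expect_lt(max(abs(G - diag(g$n_modes))), 1e-8)
  K <- kirchhoff_matrix(tr, 7.3)
  resid <- K %*% g$eigenvectors -
    g$eigenvectors %*% diag(g$eigenvalues, g$n_modes)
  expect_lt(max(abs(resid)), 1e-8)

  a <- build_anm(tr, 13)
  A <- crossprod(a$eigenvectors)
  expect_lt(max(abs(A - diag(a$n_modes))), 1e-8)
  H <- anm_hessian(trace_coords(tr), 13)
  resid2 <- H %*% a$eigenvectors -
    a$eigenvectors %*% diag(a$eigenvalues, a$n_modes)
  expect_lt(max(abs(resid2)), 1e-8)
})

test_that("disconnected networks are rejected with a component report", {
  tr <- toy_trace(cbind(c(0, 4, 50, 54), 0, 0))
  expect_error(build_gnm(tr, 7.3), "2 components")
  expect_error(build_anm(tr, 13), "2 components")
})

test_that("mobility profiles normalize and match the path-mode oracle", {
  tr <- toy_trace(cbind(c(0, 4, 8), 0, 0))
  g <- build_gnm(tr, 7.3)
  # mode 1 of the 3-path: eigenvector (1, 0, -1)/sqrt(2)
  p1 <- mobility_profile(g, m = 1)
  expect_equal(p1$values, c(0.5, 0, 0.5), tolerance = 1e-10)
  expect_equal(sum(p1$values), 1, tolerance = 1e-8)

  cloud <- toy_cloud(15, seed = 4)
  for (spec in list(build_gnm(cloud, 7.3), build_anm(cloud, 13))) {
    for (m in c(1, 3, spec$n_modes)) {
      p <- mobility_profile(spec, m = m)
      expect_equal(sum(p$values), 1, tolerance = 1e-8)
      expect_true(all(p$values >= 0))
    }
  }
  expect_error(mobility_profile(g, m = 99), "must be in")
})

test_that("mode overlap is 1 along a mode, 0 orthogonal to it", {
  a <- build_anm(toy_cloud(10, seed = 13), 13)
  v1 <- a$eigenvectors[, 1]
  expect_equal(mode_overlap(a, 1, 3.7 * v1), 1, tolerance = 1e-10)
  expect_equal(mode_overlap(a, 2, v1), 0, tolerance = 1e-10)
  expect_error(mode_overlap(a, 1, numeric(30) * 0), "zero norm")
  expect_error(mode_overlap(a, 1, rnorm(7)), "dimension mismatch")
})

test_that("cumulative overlap is monotone and reaches 1 over all modes", {
  set.seed(31)
  a <- build_anm(toy_cloud(10, seed = 13), 13)
  # an internal deformation (no rigid-body component)
  d <- as.vector(a$eigenvectors %*% rnorm(a$n_modes))
  co <- vapply(seq_len(a$n_modes), function(m) cumulative_overlap(a, m, d),
               numeric(1))
  expect_true(all(diff(co) >= -1e-12))
  expect_equal(co[a$n_modes], 1, tolerance = 1e-8)
  # a displacement containing rigid-body motion stays below 1
  d_rigid <- d + rep(c(5, 0, 0), 10)
  expect_lt(cumulative_overlap(a, a$n_modes, d_rigid), 1)

  tab <- overlap_table(a, d, m_max = 10)
  expect_equal(tab$cumulative_overlap, sqrt(cumsum(tab$overlap^2)))
})

test_that("random directions have mean squared single-mode overlap 1/(3n-6)", {
  a <- build_anm(toy_cloud(10, seed = 13), 13)
  set.seed(123)
  draws <- 2000
  sq <- replicate(draws, {
    d <- rnorm(30)
    # restrict to the internal-motion subspace spanned by the modes
    mode_overlap(a, 1, d)^2 / cumulative_overlap(a, a$n_modes, d)^2
  })
  expected <- 1 / a$n_modes
  se <- stats::sd(sq) / sqrt(draws)
  expect_lt(abs(mean(sq) - expected), 2.5 * se + 1e-4)
})
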