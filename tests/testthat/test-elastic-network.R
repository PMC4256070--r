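# GNM/ANM construction and spectral machinery against closed forms and
# svd/numeric-differentiation oracles.

test_that("two-node Kirchhoff matrix is forced by the definition", {
  s <- coarse_structure(data.frame(chain = "A", resno = 1:2,
                                   x = c(0, 5), y = 0, z = 0))
  g <- build_kirchhoff(s, 10)
  expect_equal(unname(g$matrix), matrix(c(1, -1, -1, 1), 2, 2))
})

test_that("path and ring spectra match closed forms", {
  s3 <- coarse_structure(data.frame(chain = "A", resno = 1:3,
                                    x = c(0, 8, 16), y = 0, z = 0))
  d3 <- decompose(build_kirchhoff(s3, 10))
  expect_equal(d3$zero_mode_count, 1L)
  expect_equal(d3$values, c(0, 1, 3), tolerance = 1e-10)

  # cycle graph: eigenvalues 2 - 2 cos(2 pi k / n)
  for (n in c(4L, 6L)) {
    ring <- make_ring(n, spacing = 3.8)
    d <- decompose(build_kirchhoff(ring, 4))
    expected <- sort(2 - 2 * cos(2 * pi * (seq_len(n) - 1L) / n))
    expect_equal(d$values, expected, tolerance = 1e-10)
  }
})

test_that("Kirchhoff rows and Hessian block rows sum to zero", {
  g <- build_kirchhoff(cloud30, 10)
  expect_equal(max(abs(rowSums(g$matrix))), 0)
  h <- build_hessian(cloud30, 15)
  brs <- sapply(seq_len(30), function(i) {
    rows <- (3 * i - 2):(3 * i)
    blk <- matrix(0, 3, 3)
    for (j in seq_len(30)) blk <- blk + h$matrix[rows, (3 * j - 2):(3 * j)]
    max(abs(blk))
  })
  expect_lt(max(brs), 1e-12)
})

test_that("ANM Hessian equals the numeric Hessian of the pair energy", {
  s <- make_cloud(6L, seed = 3, radius = 5)
  h <- build_hessian(s, 50)
  X0 <- coords(s)
  Hnum <- numeric_hessian(function(x) anm_pair_energy(x, X0, 50),
                          as.vector(t(X0)))
  expect_lt(max(abs(h$matrix - Hnum)) / max(abs(h$matrix)), 1e-5)
})

test_that("connected ANM networks have exactly six zero modes", {
  for (s in list(cloud30, make_helix_bundle_tetramer(15L))) {
    d <- decompose(build_hessian(s, 15))
    expect_equal(d$zero_mode_count, 6L)
  }
})

test_that("two-node ANM fluctuates only along the inter-node axis", {
  s <- coarse_structure(data.frame(chain = "A", resno = 1:2,
                                   x = c(0, 5), y = 0, z = 0))
  expect_warning(h <- build_hessian(s, 10), "collinear")
  e <- eigen(h$matrix, symmetric = TRUE)
  nz <- e$values > 1e-8
  expect_equal(sum(nz), 1L)
  u <- matrix(e$vectors[, nz], ncol = 3, byrow = TRUE)
  # displacement is along x for both nodes
  expect_lt(max(abs(u[, 2:3])), 1e-9)
})

test_that("disconnected graphs warn and gain zero modes", {
  s <- coarse_structure(data.frame(chain = "A", resno = 1:4,
                                   x = c(0, 4, 100, 104), y = 0, z = 0))
  expect_warning(g <- build_kirchhoff(s, 10), "disconnected")
  d <- decompose(g)
  expect_equal(d$zero_mode_count, 2L)
})

test_that("decompose rejects non-PSD input", {
  g <- build_kirchhoff(cloud30, 10)
  g$matrix[1, 1] <- -5
  g$matrix[2, 2] <- -5
  expect_error(decompose(g), "not PSD")
})

test_that("GNM correlations equal scale times the pseudoinverse", {
  # forced 2-node example: 3 * pinv(Gamma) = 3/4 [[1,-1],[-1,1]]
  s <- coarse_structure(data.frame(chain = "A", resno = 1:2,
                                   x = c(0, 5), y = 0, z = 0))
  d <- decompose(build_kirchhoff(s, 10))
  cc <- gnm_correlation(d, "all")
  expect_equal(unname(cc), matrix(c(0.75, -0.75, -0.75, 0.75), 2, 2),
               tolerance = 1e-10)
  # svd-pseudoinverse oracle on random instances
  for (seed in c(11, 12)) {
    s <- make_cloud(40L, seed = seed)
    # a sparse cloud may be disconnected; the pseudoinverse identity holds
    # regardless of the number of zero modes
    g <- suppressWarnings(build_kirchhoff(s, 10))
    cc <- gnm_correlation(decompose(g), "all")
    expect_lt(max(abs(cc - 3 * pinv_svd(g$matrix))), 1e-8)
  }
})

test_that("ANM correlations equal trace-of-blocks of the pseudoinverse", {
  s <- make_cloud(15L, seed = 5)
  net <- suppressWarnings(build_hessian(s, 15))
  d <- decompose(net)
  cc <- anm_correlation(d, "all")
  P <- pinv_svd(net$matrix)
  oracle <- sapply(seq_len(15), function(j) sapply(seq_len(15), function(i) {
    sum(diag(P[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)]))
  }))
  expect_lt(max(abs(cc - oracle)), 1e-8)
})

test_that("single-mode ANM maps satisfy Cauchy-Schwarz", {
  d <- decompose(build_hessian(cloud30, 15))
  m <- anm_correlation(d, 1)
  lhs <- m^2
  rhs <- outer(diag(m), diag(m))
  expect_lt(max(lhs - rhs), 1e-10)
})

test_that("normalized cross-correlations have unit diagonal and [-1,1] range", {
  d <- decompose(build_kirchhoff(cloud30, 10))
  ncc <- normalized_cross_correlation(gnm_correlation(d, "all"))
  expect_equal(unname(diag(ncc)), rep(1, 30))
  expect_lte(max(ncc), 1 + 1e-12)
  expect_gte(min(ncc), -1 - 1e-12)
  # two-node single-mode network: perfectly anticorrelated pair
  s2 <- coarse_structure(data.frame(chain = "A", resno = 1:2,
                                    x = c(0, 5), y = 0, z = 0))
  d2 <- decompose(build_kirchhoff(s2, 10))
  ncc2 <- normalized_cross_correlation(gnm_correlation(d2, 1))
  expect_equal(ncc2[1, 2], -1, tolerance = 1e-12)
})

test_that("mode contributions follow inverse-eigenvalue weighting", {
  ring <- make_ring(6L, spacing = 3.8)
  d <- decompose(build_kirchhoff(ring, 4))
  # non-zero spectrum {1,1,3,3,4}: slowest contributes 100/(2 + 2/3 + 1/4)
  expect_equal(mode_contribution(d, 1), 100 / (2 + 2 / 3 + 1 / 4),
               tolerance = 1e-9)
  expect_equal(sum(mode_contribution(d, seq_len(n_modes(d)))), 100,
               tolerance = 1e-9)
  # literal convention weights by the eigenvalues themselves
  # (non-zero spectrum sums to 12)
  expect_equal(mode_contribution(d, 1, convention = "literal"), 100 / 12,
               tolerance = 1e-9)
  expect_error(mode_contribution(d, 0), "out of range")
})

test_that("C4 symmetry produces degenerate pairs and equal chain profiles", {
  d <- decompose(build_kirchhoff(bundle40, 10))
  gr <- degenerate_groups(d)[1:8]
  expect_gte(sum(table(gr) == 2), 2)
  msf <- mean_square_fluctuation(d, "all")
  per_chain <- matrix(msf, ncol = 4L)
  expect_lt(max(abs(per_chain - per_chain[, 1])), 1e-8)
  # chain-permutation invariance of the correlation map
  cc <- gnm_correlation(d, "all")
  n <- 40L
  perm <- c((n + 1):(4 * n), 1:n)   # rotate chains by one position
  expect_lt(max(abs(cc[perm, perm] - cc)), 1e-7)
})

test_that("decomposition is deterministic including eigenvector signs", {
  d1 <- decompose(build_kirchhoff(bundle40, 10))
  d2 <- decompose(build_kirchhoff(bundle40, 10))
  expect_identical(d1$vectors, d2$vectors)
})
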