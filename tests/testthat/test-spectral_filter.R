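# Cotangent/lumped-mass operators and the manifold harmonic transform.

test_that("cotangent weights match a hand computation on equilateral triangles", {
  s3 <- sqrt(3)
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, s3 / 2, 0), c(0.5, -s3 / 2, 0))
  f <- rbind(c(1L, 2L, 3L), c(2L, 1L, 4L))
  mesh <- cortical_mesh(v, f, validate = FALSE)
  ops <- build_operators(mesh)
  K <- as.matrix(ops$stiffness)
  # interior edge (1,2): two opposite 60-degree angles -> (cot60+cot60)/2
  expect_equal(K[1, 2], -1 / s3, tolerance = 1e-12)
  # boundary edge (1,3): single opposite angle -> cot60/2
  expect_equal(K[1, 3], -1 / (2 * s3), tolerance = 1e-12)
  expect_equal(K, t(K))
  # rows sum to zero: constants are harmonic
  expect_lt(max(abs(K %*% rep(1, 4))), 1e-12)
  # lumped masses: each triangle area sqrt(3)/4 split equally over corners
  expect_equal(sum(ops$masses), 2 * s3 / 4, tolerance = 1e-12)
  expect_equal(ops$masses[1], 2 * (s3 / 4) / 3, tolerance = 1e-12)
})

test_that("vertex masses sum to the polyhedral surface area (near 4 pi r^2)", {
  m <- fix_sphere(3)
  ops <- build_operators(m)
  expect_true(all(ops$masses > 0))
  expect_equal(sum(ops$masses), mesh_area(m), tolerance = 1e-12)
  expect_lt(abs(sum(ops$masses) - 4 * pi) / (4 * pi), 0.01)
})

test_that("zero-area triangles are a hard error naming the face", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  f <- rbind(c(1L, 2L, 4L), c(1L, 2L, 3L)) # face 2 is collinear
  expect_error(build_operators(cortical_mesh(v, f, validate = FALSE)),
               "face 2", class = "atroscore_degenerate_geometry")
})

test_that("basis is mass-orthonormal with an ascending spectrum starting at zero", {
  b <- cached("basis_s2_full", compute_basis(fix_sphere(2), 162))
  expect_true(!is.unsorted(b$values))
  expect_lt(abs(b$values[1]), 1e-8 * b$values[2])
  G <- crossprod(b$vectors, b$masses * b$vectors)
  expect_lt(max(abs(G - diag(b$k))), 1e-8)
  # k = 1: constant eigenvector 1/sqrt(total mass)
  b1 <- compute_basis(fix_sphere(1), 1)
  expect_equal(b1$vectors[, 1],
               rep(1 / sqrt(sum(b1$masses)), nrow(b1$vectors)),
               tolerance = 1e-10)
})

test_that("spectrum agrees with a dense brute-force generalized eigensolve", {
  m <- fix_sphere(1) # 42 vertices
  ops <- build_operators(m)
  # independent oracle: non-symmetric dense eigensolve of M^-1 K
  ev <- eigen(diag(1 / ops$masses) %*% as.matrix(ops$stiffness))
  oracle_vals <- sort(Re(ev$values))
  b <- compute_basis(m, 42)
  expect_equal(b$values, oracle_vals, tolerance = 1e-6)
  # filtered maps agree with projection through the oracle's eigenvectors
  f <- with_seed(4, rnorm(42))
  # cut at a spectral-block boundary (1+3+5 modes) so the compared
  # projectors span the same near-degenerate eigenspaces
  k <- 9L
  ord <- order(Re(ev$values))
  phi <- Re(ev$vectors[, ord[seq_len(k)]])
  # M-orthogonal projector onto span(phi) via the Gram inverse; the raw
  # eigenvectors of M^-1 K need not be M-orthonormal inside exactly
  # degenerate (icosahedral-symmetry) blocks
  gram <- crossprod(phi, ops$masses * phi)
  oracle_filtered <- phi %*% solve(gram, crossprod(phi, ops$masses * f))
  expect_equal(lowpass_filter(b, f, k), as.numeric(oracle_filtered),
               tolerance = 1e-6)
})

test_that("unit-sphere eigenvalues approximate l(l+1) and scale with 1/r^2", {
  b <- cached("basis_s3_16", compute_basis(fix_sphere(3), 16))
  analytic <- rep(c(0, 2, 6, 12), c(1, 3, 5, 7))
  expect_lt(max(abs(b$values[-1] - analytic[-1]) / analytic[-1]), 0.05)
  bR <- compute_basis(make_icosphere(3, radius = 2), 16)
  expect_equal(bR$values[-1], b$values[-1] / 4, tolerance = 1e-8)
  # resolution consistency: s=3 approximates l(l+1) better than s=2
  b2 <- cached("basis_s2_full", compute_basis(fix_sphere(2), 162))
  err2 <- max(abs(b2$values[2:16] - analytic[-1]) / analytic[-1])
  err3 <- max(abs(b$values[-1] - analytic[-1]) / analytic[-1])
  expect_lt(err3, err2)
})

test_that("forward transform projects under the mass inner product", {
  b <- cached("basis_s2_full", compute_basis(fix_sphere(2), 162))
  tot <- sum(b$masses)
  co <- mht_forward(b, rep(3.1, 162))
  expect_equal(co[1], 3.1 * sqrt(tot), tolerance = 1e-8)
  expect_lt(max(abs(co[-1])), 1e-8)
  # an eigenvector maps to the matching unit coefficient vector
  co3 <- mht_forward(b, b$vectors[, 4])
  e4 <- replace(numeric(162), 4, 1)
  expect_equal(co3, e4, tolerance = 1e-8)
  # inverse of the scaled constant-mode coefficient is the constant map
  expect_equal(mht_inverse(b, c(2.5 * sqrt(tot))), rep(2.5, 162),
               tolerance = 1e-8)
  expect_equal(mht_inverse(b, numeric(5)), numeric(162))
})

test_that("full-basis round trip is the identity; truncation is a projection", {
  b <- cached("basis_s2_full", compute_basis(fix_sphere(2), 162))
  f <- with_seed(3, rnorm(162, mean = 2.5))
  back <- mht_inverse(b, mht_forward(b, f))
  expect_lt(max(abs(back - f)) / max(abs(f)), 1e-6)
  expect_lt(max(abs(lowpass_filter(b, f, 162) - f)) / max(abs(f)), 1e-6)

  # phi_2 + phi_(k+5) filtered at k leaves phi_2 alone
  k <- 20L
  g <- b$vectors[, 3] + b$vectors[, k + 5L]
  expect_equal(lowpass_filter(b, g, k), b$vectors[, 3], tolerance = 1e-8)

  # idempotence and energy non-increase
  lp <- lowpass_filter(b, f, 30)
  expect_lt(max(abs(lowpass_filter(b, lp, 30) - lp)), 1e-10)
  energy <- function(x) sum(b$masses * x^2)
  expect_lte(energy(lp), energy(f) + 1e-12)
  expect_error(lowpass_filter(b, f, 163), class = "atroscore_argument_error")
})

test_that("low-pass filtering denoises smooth signals corrupted by white noise", {
  b <- cached("basis_s2_full", compute_basis(fix_sphere(2), 162))
  smooth <- 2.5 + b$vectors[, 2] + 0.5 * b$vectors[, 6]
  wins <- vapply(1:20, function(s) {
    noisy <- smooth + with_seed(100 + s, rnorm(162, 0, 0.2))
    filt <- lowpass_filter(b, noisy, 10)
    rmse <- function(x) sqrt(mean((x - smooth)^2))
    rmse(filt) < rmse(noisy)
  }, logical(1))
  expect_true(all(wins))
})

test_that("matrix filtering matches per-map filtering and basis io round-trips", {
  b <- cached("basis_s2_full", compute_basis(fix_sphere(2), 162))
  X <- with_seed(8, matrix(rnorm(5 * 162, 2.5, 0.3), 5))
  fx <- lowpass_filter_matrix(b, X, 25)
  expect_equal(fx[3, ], lowpass_filter(b, X[3, ], 25), tolerance = 1e-12)
  tmp <- withr::local_tempfile()
  write_basis(b, tmp)
  b2 <- read_basis(tmp)
  expect_identical(b2$values, b$values)
  expect_identical(b2$mesh_fingerprint, b$mesh_fingerprint)
})
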