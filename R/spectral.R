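# Laplace-Beltrami spectral machinery: cotangent stiffness + lumped mass
# operators, the manifold harmonic basis, forward/inverse transforms and the
# low-pass noise filter applied to per-vertex thickness before any
# statistical modelling.
#
# Discretization: cotangent weights for the stiffness matrix K (symmetric
# PSD, zero row sums) and barycentric lumped triangle areas for the diagonal
# mass matrix M. Harmonics solve K phi = lambda M phi; eigenvectors are
# orthonormal under the mass inner product <f, g>_M = sum_v m_v f_v g_v.

#' Build the discrete Laplace-Beltrami operators for a mesh
#'
#' @param mesh a `cortical_mesh`.
#' @return a list with `stiffness` (sparse symmetric `dgCMatrix`, 1/1 units;
#'   zero row sums) and `masses` (positive per-vertex lumped areas, mm^2,
#'   summing to the total surface area).
#' @export
build_operators <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  areas <- triangle_areas(mesh)
  tiny <- 1e-12 * max(areas)
  bad <- which(areas <= tiny)
  if (length(bad) > 0L)
    abort("degenerate_geometry",
          sprintf("zero-area triangle at face %d", bad[1L]), face = bad[1L])

  # cotangent at corner a of triangle (a, b, c): dot(b-a, c-a) / (2 * area)
  corner_cot <- function(a, b, c) {
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
    rowSums(u * w) / (2 * areas)
  }
  cot1 <- corner_cot(f[, 1L], f[, 2L], f[, 3L]) # opposite edge (2,3)
  cot2 <- corner_cot(f[, 2L], f[, 3L], f[, 1L]) # opposite edge (3,1)
  cot3 <- corner_cot(f[, 3L], f[, 1L], f[, 2L]) # opposite edge (1,2)

  i <- c(f[, 2L], f[, 3L], f[, 3L], f[, 1L], f[, 1L], f[, 2L])
  j <- c(f[, 3L], f[, 2L], f[, 1L], f[, 3L], f[, 2L], f[, 1L])
  w <- c(cot1, cot1, cot2, cot2, cot3, cot3) / 2
  n <- mesh$n_vertices
  off <- Matrix::sparseMatrix(i = i, j = j, x = -w, dims = c(n, n))
  K <- off - Matrix::Diagonal(n, x = Matrix::rowSums(off))

  masses <- as.numeric(Matrix::sparseMatrix(
    i = as.vector(f), j = rep(1L, 3L * nrow(f)),
    x = rep(areas / 3, 3L), dims = c(n, 1L)))
  list(stiffness = methods::as(K, "CsparseMatrix"), masses = masses)
}

#' Compute the manifold harmonic basis of a mesh
#'
#' Solves the generalized symmetric eigenproblem `K phi = lambda M phi` for
#' the `k` smallest eigenvalues via the mass-symmetrized dense operator
#' `M^{-1/2} K M^{-1/2}`. Eigenvalues are ascending and the first is zero
#' (constants are harmonic on a closed surface). Eigenvector signs follow a
#' fixed convention so coefficients are reproducible across solvers: the
#' constant mode has positive mass-weighted sum, every other mode has its
#' first non-negligible entry positive.
#'
#' @param mesh a `cortical_mesh`.
#' @param k number of modes to retain, `1 <= k <= n_vertices`.
#' @return an object of class `spectral_basis`: `values` (ascending, 1/mm^2),
#'   `vectors` (n x k, mass-orthonormal), `masses`, `k`, `mesh_fingerprint`.
#' @export
compute_basis <- function(mesh, k) {
  n <- mesh$n_vertices
  if (k < 1L || k > n)
    abort("argument_error",
          sprintf("k = %d outside [1, %d]", k, n))
  ops <- build_operators(mesh)
  s <- 1 / sqrt(ops$masses)
  A <- as.matrix(ops$stiffness) * outer(s, s)
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  idx <- n:(n - k + 1L) # eigen() sorts descending
  vals <- e$values[idx]
  vecs <- e$vectors[, idx, drop = FALSE]
  vals[vals < 0 & vals > -1e-8 * max(abs(vals))] <- 0
  phi <- vecs * s

  for (m in seq_len(k)) {
    if (m == 1L) {
      sgn <- sum(ops$masses * phi[, 1L])
    } else {
      col <- phi[, m]
      lead <- which(abs(col) > 1e-8 * max(abs(col)))[1L]
      sgn <- col[lead]
    }
    if (sgn < 0) phi[, m] <- -phi[, m]
  }

  structure(
    list(values = vals, vectors = phi, masses = ops$masses, k = k,
         mesh_fingerprint = mesh_fingerprint(mesh)),
    class = "spectral_basis"
  )
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("spectral_basis: %d modes on %d vertices; lambda in [%.3g, %.3g]\n",
              x$k, nrow(x$vectors), x$values[1L], x$values[x$k]))
  invisible(x)
}

as_map_values <- function(map, n, what = "map") {
  vals <- if (inherits(map, "thickness_map")) map$values else as.numeric(map)
  if (length(vals) != n)
    abort("alignment_error",
          sprintf("%s has %d values but basis has %d vertices", what,
                  length(vals), n))
  vals
}

#' Forward manifold harmonic transform
#'
#' Projects a per-vertex field onto the harmonic basis under the mass inner
#' product: `c_i = sum_v m_v phi_i(v) f(v)`.
#'
#' @param basis a `spectral_basis`.
#' @param map a `thickness_map` or numeric vector aligned to the basis mesh.
#' @return numeric vector of `basis$k` spectral coefficients.
#' @export
mht_forward <- function(basis, map) {
  f <- as_map_values(map, nrow(basis$vectors))
  as.numeric(crossprod(basis$vectors, basis$masses * f))
}

#' Inverse manifold harmonic transform
#'
#' Reconstructs a per-vertex field from spectral coefficients:
#' `f(v) = sum_i c_i phi_i(v)`. Fewer coefficients than basis modes are
#' treated as a truncated (low-pass) reconstruction.
#'
#' @param basis a `spectral_basis`.
#' @param coeffs numeric coefficient vector, `length(coeffs) <= basis$k`.
#' @return numeric per-vertex field.
#' @export
mht_inverse <- function(basis, coeffs) {
  kc <- length(coeffs)
  if (kc < 1L || kc > basis$k)
    abort("alignment_error",
          sprintf("%d coefficients for a %d-mode basis", kc, basis$k))
  as.numeric(basis$vectors[, seq_len(kc), drop = FALSE] %*% coeffs)
}

#' Low-pass filter a thickness map in the harmonic domain
#'
#' The denoising step of the pipeline: thickness is mapped to the frequency
#' domain, components above `k_keep` are discarded as noise, and the field is
#' reconstructed from the retained low-frequency modes. The operation is an
#' orthogonal projection under the mass inner product, hence idempotent and
#' energy non-increasing.
#'
#' @param basis a `spectral_basis` with at least `k_keep` modes.
#' @param map `thickness_map` or numeric vector.
#' @param k_keep number of low-frequency modes to retain.
#' @return numeric filtered per-vertex field (same length as input).
#' @export
lowpass_filter <- function(basis, map, k_keep) {
  if (k_keep < 1L || k_keep > basis$k)
    abort("argument_error",
          sprintf("k_keep = %d outside [1, %d]", k_keep, basis$k))
  coeffs <- mht_forward(basis, map)
  mht_inverse(basis, coeffs[seq_len(k_keep)])
}

#' Low-pass filter a cohort thickness matrix
#'
#' Convenience vectorization of [lowpass_filter()] over the rows of a
#' subjects-by-vertices matrix.
#'
#' @param basis a `spectral_basis`.
#' @param thickness numeric matrix, one subject per row.
#' @param k_keep modes to retain.
#' @return filtered matrix of the same shape.
#' @export
lowpass_filter_matrix <- function(basis, thickness, k_keep) {
  if (k_keep < 1L || k_keep > basis$k)
    abort("argument_error",
          sprintf("k_keep = %d outside [1, %d]", k_keep, basis$k))
  if (ncol(thickness) != nrow(basis$vectors))
    abort("alignment_error",
          sprintf("matrix has %d columns but basis has %d vertices",
                  ncol(thickness), nrow(basis$vectors)))
  phi <- basis$vectors[, seq_len(k_keep), drop = FALSE]
  coeffs <- thickness %*% (basis$masses * phi)
  out <- coeffs %*% t(phi)
  dimnames(out) <- dimnames(thickness)
  out
}

#' Serialize a spectral basis to a file
#'
#' Stored as an RDS archive (eigenvalues, eigenvectors, masses, mesh
#' fingerprint) so one basis is computed per mesh and reused across a cohort.
#'
#' @param basis a `spectral_basis`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_basis <- function(basis, path) {
  saveRDS(basis, path, version = 2)
  invisible(path)
}

#' Read a serialized spectral basis
#'
#' @param path path written by [write_basis()].
#' @return a `spectral_basis`.
#' @export
read_basis <- function(path) {
  basis <- readRDS(path)
  if (!inherits(basis, "spectral_basis"))
    abort("format_error", sprintf("%s does not contain a spectral_basis",
                                  path))
  basis
}
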