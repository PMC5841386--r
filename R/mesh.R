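# Triangulated cortical surface meshes: construction, validation, icospheres.
#
# A cortical_mesh stores vertex coordinates in mm and faces as 1-based vertex
# index triples (file dialects that index from 0 are converted at the I/O
# boundary). All spectral operations assume an edge-manifold, consistently
# oriented triangulation.

#' Construct a cortical surface mesh
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param hemisphere one of `"left"`, `"right"`, `"synthetic"`.
#' @param validate if `TRUE` (default) run [validate_mesh()] and fail on any
#'   violation.
#' @return an object of class `cortical_mesh` with elements `vertices`,
#'   `faces`, `hemisphere`, `n_vertices`, `n_faces`.
#' @export
cortical_mesh <- function(vertices, faces, hemisphere = "synthetic",
                          validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L)
    abort("argument_error", "vertices must have 3 columns (x, y, z)")
  if (ncol(faces) != 3L)
    abort("argument_error", "faces must have 3 columns")
  hemisphere <- match.arg(hemisphere, c("left", "right", "synthetic"))
  mesh <- structure(
    list(vertices = vertices, faces = faces, hemisphere = hemisphere,
         n_vertices = nrow(vertices), n_faces = nrow(faces)),
    class = "cortical_mesh"
  )
  if (validate) {
    report <- validate_mesh(mesh)
    if (nrow(report) > 0L) {
      abort("validation_error",
            paste0("invalid mesh: ",
                   paste(utils::head(report$message, 5L), collapse = "; ")),
            report = report)
    }
  }
  mesh
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat(sprintf("cortical_mesh: %d vertices, %d faces (%s hemisphere)\n",
              x$n_vertices, x$n_faces, x$hemisphere))
  invisible(x)
}

#' Validate a cortical surface mesh
#'
#' Checks the structural invariants every downstream operation relies on:
#' face indices in range, no degenerate (repeated-index) triangles,
#' edge-manifoldness (each undirected edge on at most two faces), and
#' consistent face orientation (no directed edge traversed twice in the same
#' direction).
#'
#' @param mesh a `cortical_mesh` (or a bare list with `vertices`/`faces`).
#' @return a data frame with columns `type`, `face`, `message`; zero rows iff
#'   the mesh is valid.
#' @export
validate_mesh <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  viol <- list()
  add <- function(type, face, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      type = type, face = face, message = message,
      stringsAsFactors = FALSE)
  }

  bad_idx <- which(f < 1L | f > nv, arr.ind = TRUE)
  if (nrow(bad_idx) > 0L) {
    for (r in unique(bad_idx[, 1L]))
      add("index_out_of_range", r,
          sprintf("face %d has vertex index outside [1, %d]", r, nv))
    # range errors make edge bookkeeping meaningless; stop here
    return(do.call(rbind, viol))
  }

  degen <- which(f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L])
  for (r in degen)
    add("degenerate_face", r, sprintf("face %d repeats a vertex index", r))

  # directed half-edges; manifold + orientation checks on the edge multiset
  he_from <- c(f[, 1L], f[, 2L], f[, 3L])
  he_to <- c(f[, 2L], f[, 3L], f[, 1L])
  he_face <- rep.int(seq_len(nrow(f)), 3L)
  ekey <- paste(pmin(he_from, he_to), pmax(he_from, he_to))
  cnt <- table(ekey)
  over <- names(cnt)[cnt > 2L]
  for (e in over) {
    faces_on <- sort(unique(he_face[ekey == e]))
    add("edge_manifold", faces_on[1L],
        sprintf("undirected edge (%s) shared by %d half-edges (faces %s)",
                gsub(" ", ",", e), cnt[[e]],
                paste(faces_on, collapse = ",")))
  }
  dkey <- paste(he_from, he_to)
  dcnt <- table(dkey)
  dup_dir <- names(dcnt)[dcnt > 1L]
  for (e in dup_dir) {
    faces_on <- sort(unique(he_face[dkey == e]))
    add("orientation", faces_on[length(faces_on)],
        sprintf("directed edge (%s) traversed twice in the same direction by faces %s",
                gsub(" ", ",", e), paste(faces_on, collapse = ",")))
  }

  if (length(viol) == 0L) {
    data.frame(type = character(), face = integer(), message = character(),
               stringsAsFactors = FALSE)
  } else {
    unique(do.call(rbind, viol))
  }
}

# base icosahedron: 12 vertices, 20 consistently outward-wound faces
icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- matrix(c(
    -1,  t,  0,   1,  t,  0,  -1, -t,  0,   1, -t,  0,
     0, -1,  t,   0,  1,  t,   0, -1, -t,   0,  1, -t,
     t,  0, -1,   t,  0,  1,  -t,  0, -1,  -t,  0,  1
  ), ncol = 3L, byrow = TRUE)
  f <- matrix(c(
    1, 12, 6,  1, 6, 2,   1, 2, 8,   1, 8, 11,  1, 11, 12,
    2, 6, 10,  6, 12, 5,  12, 11, 3, 11, 8, 7,  8, 2, 9,
    4, 10, 5,  4, 5, 3,   4, 3, 7,   4, 7, 9,   4, 9, 10,
    5, 10, 6,  3, 5, 12,  7, 3, 11,  9, 7, 8,   10, 9, 2
  ), ncol = 3L, byrow = TRUE)
  list(vertices = v / sqrt(1 + t^2), faces = f)
}

#' Generate an icosphere mesh
#'
#' Recursively subdivides an icosahedron and projects vertices to a sphere of
#' the requested radius. Subdivision level `s` yields `10 * 4^s + 2` vertices
#' and `20 * 4^s` faces; level 6 gives 40,962 vertices, the per-hemisphere
#' resolution used for registered cortical surfaces.
#'
#' @param subdivisions integer >= 0, number of 4-to-1 subdivisions.
#' @param radius sphere radius (mm).
#' @param max_subdivisions refusal cap on `subdivisions` (default 7).
#' @return a `cortical_mesh` (hemisphere `"synthetic"`).
#' @export
make_icosphere <- function(subdivisions, radius = 1, max_subdivisions = 7L) {
  if (length(subdivisions) != 1L || is.na(subdivisions) || subdivisions < 0)
    abort("argument_error", "subdivisions must be a single integer >= 0")
  if (subdivisions > max_subdivisions)
    abort("argument_error",
          sprintf("subdivisions = %d exceeds cap %d", subdivisions,
                  max_subdivisions))
  base <- icosahedron()
  v <- base$vertices
  f <- base$faces
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    # unique undirected edges -> one midpoint vertex each
    e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
    e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    key <- (e[, 1L] - 1) * nv + e[, 2L]
    ukey <- unique(key)
    mid_id <- match(key, ukey) + nv
    ue <- e[match(ukey, key), , drop = FALSE]
    mids <- (v[ue[, 1L], , drop = FALSE] + v[ue[, 2L], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2L * nf + seq_len(nf)]
    f <- rbind(
      cbind(f[, 1L], m12, m31),
      cbind(m12, f[, 2L], m23),
      cbind(m31, m23, f[, 3L]),
      cbind(m12, m23, m31)
    )
  }
  cortical_mesh(v * radius, f, hemisphere = "synthetic", validate = FALSE)
}

# undirected edge list (2-column matrix, each edge once)
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
}

#' Total surface area of a mesh
#'
#' @param mesh a `cortical_mesh`.
#' @return summed triangle areas (mm^2).
#' @export
mesh_area <- function(mesh) {
  sum(triangle_areas(mesh))
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cr <- cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
              a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
              a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  0.5 * sqrt(rowSums(cr^2))
}

#' Fingerprint a mesh
#'
#' Stable md5 digest of the vertex coordinates and face table, used to check
#' that spectral bases, normative models and classifiers built on one mesh
#' are not applied to another.
#'
#' @param mesh a `cortical_mesh`.
#' @return a length-1 character md5 string.
#' @export
mesh_fingerprint <- function(mesh) {
  object_fingerprint(list(v = mesh$vertices, f = mesh$faces))
}
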