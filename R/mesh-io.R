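# Readers and writers for surface meshes and per-vertex morphometry.
#
# Dialects:
#   * freesurfer_binary / freesurfer_curv - the big-endian binary formats
#     written by FreeSurfer (triangle-file magic 0xFFFFFE, curv "new format"
#     magic 0xFFFFFF). Faces are 0-based on disk and converted to 1-based.
#   * internal - a documented plain-text format so fixtures and artifacts are
#     human-readable and survive text-only transport. Full double precision
#     ("%.17g") so internal round trips are exact.
#   * csv (morphometry only) - single "value" column with header.

FS_TRIANGLE_MAGIC <- 16777214L # 0xFFFFFE
FS_CURV_MAGIC <- 16777215L     # 0xFFFFFF

read_int24 <- function(con) {
  b <- readBin(con, "integer", n = 3L, size = 1L, signed = FALSE)
  if (length(b) < 3L) return(NA_integer_)
  b[1L] * 65536L + b[2L] * 256L + b[3L]
}

write_int24 <- function(con, x) {
  writeBin(as.integer(c(x %/% 65536L, (x %/% 256L) %% 256L, x %% 256L)),
           con, size = 1L)
}

#' Construct a per-vertex thickness map
#'
#' @param values numeric vector, one thickness (mm) per mesh vertex; must be
#'   finite and non-negative.
#' @param mesh optional `cortical_mesh` to check the length against.
#' @param subject_id subject identifier.
#' @param visit_time years from baseline (0 for cross-sectional data).
#' @param nonnegative enforce `values >= 0` (the thickness invariant); set
#'   `FALSE` for signed per-vertex scalars such as curvature or weight maps.
#' @return an object of class `thickness_map`.
#' @export
thickness_map <- function(values, mesh = NULL, subject_id = NA_character_,
                          visit_time = 0, nonnegative = TRUE) {
  values <- as.numeric(values)
  bad <- which(!is.finite(values))
  if (length(bad) > 0L)
    abort("data_error",
          sprintf("non-finite thickness at vertex %d", bad[1L]),
          vertex = bad[1L])
  if (nonnegative && any(values < 0))
    abort("data_error", "thickness values must be >= 0")
  if (!is.null(mesh) && length(values) != mesh$n_vertices)
    abort("alignment_error",
          sprintf("map has %d values but mesh has %d vertices",
                  length(values), mesh$n_vertices))
  structure(list(values = values, subject_id = subject_id,
                 visit_time = visit_time),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("thickness_map: %d vertices, mean %.3f mm (subject %s, t=%g y)\n",
              length(x$values), mean(x$values), x$subject_id, x$visit_time))
  invisible(x)
}

#' Read a triangulated surface mesh
#'
#' @param path file path.
#' @param dialect `"freesurfer_binary"` or `"internal"`.
#' @param hemisphere hemisphere tag to attach.
#' @param validate validate manifoldness/orientation after reading.
#' @return a `cortical_mesh`.
#' @export
read_surface <- function(path, dialect = c("internal", "freesurfer_binary"),
                         hemisphere = "synthetic", validate = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    abort("io_error", sprintf("no such file: %s", path))
  if (dialect == "freesurfer_binary") {
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    magic <- read_int24(con)
    if (is.na(magic) || magic != FS_TRIANGLE_MAGIC)
      abort("format_error",
            sprintf("%s: bad magic for freesurfer_binary surface (got %s)",
                    path, magic))
    # creator string terminated by "\n\n"
    prev <- 0L
    repeat {
      ch <- readBin(con, "integer", n = 1L, size = 1L, signed = FALSE)
      if (length(ch) == 0L)
        abort("format_error", sprintf("%s: truncated header", path))
      if (ch == 10L && prev == 10L) break
      prev <- ch
    }
    nv <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
    nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
    if (length(nv) == 0L || length(nf) == 0L || nv <= 0L || nf <= 0L)
      abort("format_error", sprintf("%s: bad vertex/face counts", path))
    coords <- readBin(con, "numeric", n = 3L * nv, size = 4L, endian = "big")
    faces <- readBin(con, "integer", n = 3L * nf, size = 4L, endian = "big")
    if (length(coords) < 3L * nv || length(faces) < 3L * nf)
      abort("format_error", sprintf("%s: truncated data section", path))
    v <- matrix(coords, ncol = 3L, byrow = TRUE)
    f <- matrix(faces, ncol = 3L, byrow = TRUE) + 1L
  } else {
    lines <- readLines(path)
    if (length(lines) < 3L || !startsWith(lines[1L], "#atroscore mesh"))
      abort("format_error",
            sprintf("%s: missing '#atroscore mesh' header for internal dialect",
                    path))
    hdr <- strsplit(lines[2L], "[[:space:]]+")[[1L]]
    nv <- as.integer(hdr[2L])
    nf <- as.integer(hdr[3L])
    hemisphere <- hdr[1L]
    if (is.na(nv) || is.na(nf))
      abort("format_error", sprintf("%s: bad counts line", path))
    if (length(lines) < 2L + nv + nf)
      abort("format_error", sprintf("%s: truncated (need %d lines)", path,
                                    2L + nv + nf))
    v <- matrix(scan(text = lines[3:(2L + nv)], quiet = TRUE),
                ncol = 3L, byrow = TRUE)
    f <- matrix(as.integer(scan(text = lines[(3L + nv):(2L + nv + nf)],
                                quiet = TRUE)),
                ncol = 3L, byrow = TRUE) + 1L
  }
  if (any(f < 1L | f > nv))
    abort("validation_error",
          sprintf("%s: face vertex index outside [0, %d)", path, nv))
  cortical_mesh(v, f, hemisphere = hemisphere, validate = validate)
}

#' Write a triangulated surface mesh
#'
#' @param mesh a `cortical_mesh`.
#' @param path output path.
#' @param dialect `"internal"` (plain text) or `"freesurfer_binary"`.
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path,
                          dialect = c("internal", "freesurfer_binary")) {
  dialect <- match.arg(dialect)
  if (dialect == "freesurfer_binary") {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    write_int24(con, FS_TRIANGLE_MAGIC)
    writeBin(charToRaw("created by atroscore\n\n"), con)
    writeBin(as.integer(c(mesh$n_vertices, mesh$n_faces)), con, size = 4L,
             endian = "big")
    writeBin(as.numeric(t(mesh$vertices)), con, size = 4L, endian = "big")
    writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4L, endian = "big")
  } else {
    lines <- c(
      "#atroscore mesh v1",
      sprintf("%s %d %d", mesh$hemisphere, mesh$n_vertices, mesh$n_faces),
      sprintf("%.17g %.17g %.17g",
              mesh$vertices[, 1L], mesh$vertices[, 2L], mesh$vertices[, 3L]),
      sprintf("%d %d %d",
              mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
              mesh$faces[, 3L] - 1L)
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a per-vertex morphometry (thickness) file
#'
#' @param path file path.
#' @param mesh `cortical_mesh` the values must align to.
#' @param dialect `"freesurfer_curv"`, `"csv"` or `"internal"`.
#' @param subject_id,visit_time metadata attached to the returned map.
#' @param signed allow negative values (curvature-like or weight maps);
#'   thickness proper must be non-negative.
#' @return a `thickness_map` aligned to `mesh` vertex order.
#' @export
read_morphometry <- function(path, mesh,
                             dialect = c("internal", "freesurfer_curv", "csv"),
                             subject_id = NA_character_, visit_time = 0,
                             signed = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    abort("io_error", sprintf("no such file: %s", path))
  if (dialect == "freesurfer_curv") {
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    magic <- read_int24(con)
    if (is.na(magic) || magic != FS_CURV_MAGIC)
      abort("format_error",
            sprintf("%s: bad magic for freesurfer_curv (got %s)", path, magic))
    nv <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
    readBin(con, "integer", n = 1L, size = 4L, endian = "big") # face count
    vpv <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
    if (length(vpv) == 0L || vpv != 1L)
      abort("format_error",
            sprintf("%s: values-per-vertex %s unsupported", path, vpv))
    values <- readBin(con, "numeric", n = nv, size = 4L, endian = "big")
    if (length(values) < nv)
      abort("format_error", sprintf("%s: truncated values", path))
  } else if (dialect == "csv") {
    d <- utils::read.csv(path)
    if (!"value" %in% names(d))
      abort("format_error", sprintf("%s: csv dialect needs a 'value' column",
                                    path))
    values <- as.numeric(d$value)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    values <- as.numeric(lines)
  }
  if (length(values) != mesh$n_vertices)
    abort("alignment_error",
          sprintf("%s: %d values but mesh has %d vertices", path,
                  length(values), mesh$n_vertices))
  thickness_map(values, mesh, subject_id = subject_id,
                visit_time = visit_time, nonnegative = !signed)
}

#' Write a per-vertex morphometry file
#'
#' @param values a `thickness_map` or numeric vector.
#' @param path output path.
#' @param dialect `"internal"`, `"freesurfer_curv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_morphometry <- function(values, path,
                              dialect = c("internal", "freesurfer_curv",
                                          "csv")) {
  dialect <- match.arg(dialect)
  if (inherits(values, "thickness_map")) values <- values$values
  values <- as.numeric(values)
  if (dialect == "freesurfer_curv") {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    write_int24(con, FS_CURV_MAGIC)
    writeBin(as.integer(c(length(values), 0L, 1L)), con, size = 4L,
             endian = "big")
    writeBin(values, con, size = 4L, endian = "big")
  } else if (dialect == "csv") {
    # full "%.17g" precision; write.csv would round to 15 significant digits
    writeLines(c("\"value\"", sprintf("%.17g", values)), path)
  } else {
    writeLines(c("#atroscore morphometry v1", sprintf("%.17g", values)), path)
  }
  invisible(path)
}

#' Read a subject covariate table
#'
#' Expects a CSV with header columns `subject_id`, `age`, `education`,
#' `diagnosis` and optionally `visit_time`, `mmse`, `cdr`, `cdr_sb`.
#' Diagnoses must be CN, AD or aMCI; ages must be positive and education
#' non-negative.
#'
#' @param path CSV path.
#' @return a data frame of subject records.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path))
    abort("io_error", sprintf("no such file: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "education", "diagnosis")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L)
    abort("format_error",
          sprintf("%s: missing columns: %s", path,
                  paste(miss, collapse = ", ")))
  if (!all(d$diagnosis %in% c("CN", "AD", "aMCI")))
    abort("data_error",
          sprintf("%s: diagnosis must be CN, AD or aMCI", path))
  if (any(!is.finite(d$age) | d$age <= 0))
    abort("data_error", sprintf("%s: ages must be positive", path))
  if (any(!is.finite(d$education) | d$education < 0))
    abort("data_error", sprintf("%s: education must be >= 0", path))
  if (!"visit_time" %in% names(d)) d$visit_time <- 0
  d
}
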