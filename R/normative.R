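# Normative w-score modelling: per-vertex OLS of (noise-filtered) cortical
# thickness on age and education, fitted on cognitively normal subjects
# only, and conversion of new maps to w-scores
#   w(v) = (observed(v) - predicted(v)) / residual SD(v),
# i.e. a covariate-adjusted z-score per vertex. More negative w-scores mean
# thinner cortex than demographically expected.

#' Fit a per-vertex normative model on cognitively normal subjects
#'
#' Ordinary least squares of thickness on `[1, age, education]` at every
#' vertex independently, with residual standard deviation on `n - 3` degrees
#' of freedom. Vertices with (numerically) zero residual variance are flagged
#' and floored at `sd_floor` rather than producing infinite w-scores.
#'
#' @param thickness numeric matrix of filtered thickness, one CN subject per
#'   row, one vertex per column.
#' @param age,education numeric covariate vectors, one entry per row of
#'   `thickness`.
#' @param min_train minimum admissible number of training subjects.
#' @param sd_floor lower bound applied to flagged residual SDs (mm).
#' @return an object of class `normative_model` with `coefficients`
#'   (3 x n_vertices: intercept, age, education), `sigma` (residual SD per
#'   vertex), `n_train`, `covariates`, `flagged_vertices`,
#'   `mesh_fingerprint` (set by callers that know the mesh, else `NA`).
#' @export
fit_normative <- function(thickness, age, education, min_train = 10L,
                          sd_floor = 1e-6) {
  thickness <- as.matrix(thickness)
  n <- nrow(thickness)
  if (length(age) != n || length(education) != n)
    abort("alignment_error",
          "age/education must have one entry per thickness row")
  if (n < min_train)
    abort("argument_error",
          sprintf("need at least %d CN training subjects, got %d",
                  min_train, n))
  X <- cbind(intercept = 1, age = as.numeric(age),
             education = as.numeric(education))
  sv <- svd(X, nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 0 || sv[1L] / sv[length(sv)] > 1e8)
    abort("conditioning_error",
          sprintf("design matrix ill-conditioned (condition number %.3g); age and education are collinear or constant",
                  if (sv[length(sv)] > 0) sv[1L] / sv[length(sv)] else Inf))
  beta <- solve(crossprod(X), crossprod(X, thickness))
  resid <- thickness - X %*% beta
  sigma <- sqrt(colSums(resid^2) / (n - 3))
  flagged <- which(sigma < sd_floor)
  if (length(flagged) > 0L) {
    warning(sprintf("%d vertices with ~zero residual variance; SD floored at %g",
                    length(flagged), sd_floor))
    sigma[flagged] <- sd_floor
  }
  structure(
    list(coefficients = beta, sigma = sigma, n_train = n,
         covariates = c("age", "education"),
         flagged_vertices = flagged,
         mesh_fingerprint = NA_character_),
    class = "normative_model"
  )
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("normative_model: %d vertices, %d CN training subjects\n",
              ncol(x$coefficients), x$n_train))
  cat(sprintf("  mean age slope %.4g mm/y, mean education slope %.4g mm/y, mean residual SD %.3g mm\n",
              mean(x$coefficients["age", ]),
              mean(x$coefficients["education", ]), mean(x$sigma)))
  invisible(x)
}

#' @export
coef.normative_model <- function(object, ...) object$coefficients

#' Predicted normative thickness for given covariates
#'
#' @param object a `normative_model`.
#' @param age,education scalar covariates (or vectors for several subjects).
#' @param ... unused.
#' @return per-vertex predicted thickness; a matrix (subjects x vertices)
#'   when covariates have length > 1.
#' @export
predict.normative_model <- function(object, age, education, ...) {
  if (missing(age) || missing(education) ||
      anyNA(age) || anyNA(education))
    abort("covariate_error", "age and education are required")
  X <- cbind(1, as.numeric(age), as.numeric(education))
  pred <- X %*% object$coefficients
  if (nrow(pred) == 1L) as.numeric(pred) else pred
}

#' Convert a filtered thickness map to w-scores
#'
#' @param model a `normative_model`.
#' @param map `thickness_map` or numeric vector of filtered thickness, or a
#'   subjects-by-vertices matrix (then `age`/`education` are vectors).
#' @param age,education subject covariates.
#' @return numeric w-score vector (or matrix for matrix input).
#' @export
compute_wscore <- function(model, map, age, education) {
  if (missing(age) || missing(education) ||
      anyNA(age) || anyNA(education))
    abort("covariate_error", "age and education are required")
  vals <- if (inherits(map, "thickness_map")) map$values else map
  nv <- ncol(model$coefficients)
  if (is.matrix(vals)) {
    if (ncol(vals) != nv)
      abort("alignment_error",
            sprintf("map has %d vertices but model has %d", ncol(vals), nv))
    pred <- cbind(1, as.numeric(age), as.numeric(education)) %*%
      model$coefficients
    sweep(vals - pred, 2L, model$sigma, "/")
  } else {
    vals <- as.numeric(vals)
    if (length(vals) != nv)
      abort("alignment_error",
            sprintf("map has %d vertices but model has %d", length(vals), nv))
    (vals - predict(model, age, education)) / model$sigma
  }
}

#' Serialize / read a normative model
#'
#' @param model a `normative_model`.
#' @param path file path.
#' @return `path` (write) or the model (read).
#' @export
write_normative <- function(model, path) {
  saveRDS(model, path, version = 2)
  invisible(path)
}

#' @rdname write_normative
#' @export
read_normative <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "normative_model"))
    abort("format_error", sprintf("%s does not contain a normative_model",
                                  path))
  model
}
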