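# Pipeline driver behind the command-line entry point (inst/cli/atroscore).
# Each subcommand reads the artifacts of the previous stage from the output
# directory, so a full analysis is
#   simulate -> fit-normative -> train -> {cross-validate, score, map}
# plus `longitudinal` for the mixed-effects validation. Artifacts embed the
# seed, a config hash and the package version; re-running a stage with the
# same config and seed reproduces its outputs byte for byte.

#' Assemble a pipeline configuration
#'
#' @param out_dir directory for stage artifacts.
#' @param seed integer seed used by every stochastic stage.
#' @param subdivisions,radius,n_cn,n_ad,patch_depth,patch_radius,noise_white_sd
#'   synthetic cohort parameters (see [cohort_spec()]).
#' @param modes number of manifold harmonics retained by the low-pass
#'   filter (default 40 at desk resolutions; the cutoff is a tunable of the
#'   method, see the vignette).
#' @param pca_dim explicit PCA dimension or `NULL` for the 90% variance rule.
#' @param var_fraction variance target for the automatic PCA rule.
#' @param folds cross-validation folds.
#' @param visits path to a visit table CSV for the `longitudinal` stage.
#' @param model `"similarity_by_time"` or `"group_by_time"`.
#' @param outcome outcome column for `similarity_by_time`.
#' @param ... additional [cohort_spec()] overrides.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, subdivisions = 3L,
                            radius = 80, n_cn = 100L, n_ad = 100L,
                            patch_depth = 0.6, patch_radius = 50,
                            noise_white_sd = 0.1, modes = 40L,
                            pca_dim = NULL, var_fraction = 0.9,
                            folds = 10L, visits = NULL,
                            model = "similarity_by_time", outcome = "mmse",
                            ...) {
  structure(c(as.list(environment()), list(...)), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    abort("io_error", sprintf("no such config: %s", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals$out_dir))
    abort("format_error", "config must set out_dir")
  do.call(pipeline_config, vals)
}

pipeline_paths <- function(config) {
  out <- config$out_dir
  list(
    mesh = file.path(out, "mesh.txt"),
    cohort = file.path(out, "cohort.csv"),
    thickness = file.path(out, "thickness.csv"),
    truth = file.path(out, "truth.json"),
    basis = file.path(out, "basis.rds"),
    normative = file.path(out, "normative.rds"),
    filtered = file.path(out, "filtered.csv"),
    classifier = file.path(out, "classifier.rds"),
    classifier_json = file.path(out, "classifier.json"),
    cv_report = file.path(out, "cv_report.json"),
    scores = file.path(out, "scores.csv"),
    dmap = file.path(out, "discriminative_map.txt"),
    lmm_report = file.path(out, "longitudinal_fit.json")
  )
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path))
    abort("dependency_error",
          sprintf("missing artifact %s; run the '%s' stage first",
                  path, produced_by))
  path
}

provenance <- function(config) {
  list(seed = config$seed,
       config_hash = object_fingerprint(unclass(config)),
       package_version = as.character(utils::packageVersion("atroscore")))
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

write_matrix_csv <- function(m, path) {
  d <- data.frame(subject_id = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
}

read_matrix_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE,
                       stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Run one pipeline stage
#'
#' @param config a [pipeline_config()] (or a YAML path).
#' @param subcommand one of `"simulate"`, `"fit-normative"`, `"train"`,
#'   `"cross-validate"`, `"score"`, `"map"`, `"longitudinal"`.
#' @return invisibly, a named list of artifact paths written by the stage.
#' @export
run_pipeline <- function(config,
                         subcommand = c("simulate", "fit-normative", "train",
                                        "cross-validate", "score", "map",
                                        "longitudinal")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  subcommand <- match.arg(subcommand)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- pipeline_paths(config)
  prov <- provenance(config)

  if (subcommand == "simulate") {
    spec <- cohort_spec(
      subdivisions = config$subdivisions, radius = config$radius,
      n_cn = config$n_cn, n_ad = config$n_ad,
      patch_depth = config$patch_depth, patch_radius = config$patch_radius,
      noise_white_sd = config$noise_white_sd, seed = config$seed)
    cohort <- generate_cohort(spec)
    write_surface(cohort$mesh, p$mesh, dialect = "internal")
    utils::write.csv(cohort$covariates, p$cohort, row.names = FALSE)
    write_matrix_csv(cohort$thickness, p$thickness)
    write_json_artifact(
      c(prov, list(patch_vertices = which(cohort$truth$patch_mask),
                   beta_age = cohort$truth$beta_age,
                   beta_edu = cohort$truth$beta_edu,
                   severity = cohort$truth$severity)),
      p$truth)
    return(invisible(p[c("mesh", "cohort", "thickness", "truth")]))
  }

  if (subcommand == "fit-normative") {
    mesh <- read_surface(require_artifact(p$mesh, "simulate"),
                         dialect = "internal")
    cov <- read_covariates(require_artifact(p$cohort, "simulate"))
    thickness <- read_matrix_csv(require_artifact(p$thickness, "simulate"))
    basis <- compute_basis(mesh, k = config$modes)
    filtered <- lowpass_filter_matrix(basis, thickness, config$modes)
    cn <- cov$diagnosis == "CN"
    norm <- fit_normative(filtered[cn, , drop = FALSE], cov$age[cn],
                          cov$education[cn])
    norm$mesh_fingerprint <- basis$mesh_fingerprint
    write_basis(basis, p$basis)
    write_matrix_csv(filtered, p$filtered)
    write_normative(norm, p$normative)
    return(invisible(p[c("basis", "filtered", "normative")]))
  }

  if (subcommand == "train") {
    cov <- read_covariates(require_artifact(p$cohort, "simulate"))
    filtered <- read_matrix_csv(require_artifact(p$filtered,
                                                 "fit-normative"))
    basis <- read_basis(require_artifact(p$basis, "fit-normative"))
    norm <- read_normative(require_artifact(p$normative, "fit-normative"))
    w <- compute_wscore(norm, filtered, cov$age, cov$education)
    clf <- train_classifier(
      w, cov$diagnosis, pca_dim = config$pca_dim,
      var_fraction = config$var_fraction,
      basis_fingerprint = object_fingerprint(unclass(basis)),
      model_fingerprint = object_fingerprint(unclass(norm)))
    write_classifier(clf, p$classifier)
    write_json_artifact(
      c(prov, list(n_cn = clf$n_cn, n_ad = clf$n_ad,
                   pca_dim = ncol(clf$rotation),
                   explained_variance = sum(clf$explained_variance),
                   proj_cn = clf$proj_cn, proj_ad = clf$proj_ad)),
      p$classifier_json)
    return(invisible(p[c("classifier", "classifier_json")]))
  }

  if (subcommand == "cross-validate") {
    cov <- read_covariates(require_artifact(p$cohort, "simulate"))
    filtered <- read_matrix_csv(require_artifact(p$filtered,
                                                 "fit-normative"))
    cv <- cross_validate(filtered, cov$age, cov$education, cov$diagnosis,
                         n_folds = config$folds, seed = config$seed,
                         pca_dim = config$pca_dim,
                         var_fraction = config$var_fraction)
    write_json_artifact(
      c(prov, list(
        n_folds = cv$n_folds,
        accuracy = cv$accuracy, sensitivity = cv$sensitivity,
        specificity = cv$specificity,
        confusion = as.list(cv$confusion),
        per_fold = lapply(cv$folds, as.list))),
      p$cv_report)
    return(invisible(p["cv_report"]))
  }

  if (subcommand == "score") {
    cov <- read_covariates(require_artifact(p$cohort, "simulate"))
    filtered <- read_matrix_csv(require_artifact(p$filtered,
                                                 "fit-normative"))
    norm <- read_normative(require_artifact(p$normative, "fit-normative"))
    clf <- read_classifier(require_artifact(p$classifier, "train"))
    w <- compute_wscore(norm, filtered, cov$age, cov$education)
    sim <- atrophy_similarity(clf, w, subject_id = cov$subject_id,
                              visit_time = cov$visit_time)
    utils::write.csv(sim, p$scores, row.names = FALSE)
    return(invisible(p["scores"]))
  }

  if (subcommand == "map") {
    clf <- read_classifier(require_artifact(p$classifier, "train"))
    dmap <- discriminative_map(clf)
    write_morphometry(dmap, p$dmap, dialect = "internal")
    return(invisible(p["dmap"]))
  }

  # longitudinal
  visits_path <- config$visits %||% abort(
    "argument_error", "config$visits (a visit-table CSV) is required")
  if (!file.exists(visits_path))
    abort("dependency_error",
          sprintf("missing visit table %s", visits_path))
  visits <- utils::read.csv(visits_path, stringsAsFactors = FALSE)
  fit <- if (config$model == "group_by_time") {
    fit_group_by_time(visits, visits[!duplicated(visits$subject_id),
                                     c("subject_id", "label")])
  } else {
    fit_similarity_by_time(visits, config$outcome)
  }
  write_json_artifact(
    c(prov, list(model = config$model,
                 outcome = fit$outcome %||% "similarity",
                 n_subjects = fit$n_subjects,
                 n_observations = fit$n_observations,
                 coefficients = fit$coefficients[,
                   c("term", "estimate", "se", "p")],
                 random_intercept_var = fit$random_intercept_var,
                 residual_var = fit$residual_var)),
    p$lmm_report)
  invisible(p["lmm_report"])
}
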