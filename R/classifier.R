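# Group classifier: PCA dimensionality reduction followed by a two-class
# Fisher linear discriminant, trained on w-score feature vectors. The LDA
# axis is the single direction maximizing between- to within-class scatter,
#   a  propto  Sw^{-1} (mu_AD - mu_CN),
# with a small ridge on the within-class scatter for invertibility when the
# retained PCA dimension approaches the sample size. The axis is oriented so
# AD projects above CN, which fixes the sign of every downstream similarity
# score and map.

check_labels <- function(labels) {
  labels <- as.character(labels)
  if (!all(labels %in% c("CN", "AD")))
    abort("label_error", "labels must be 'CN' or 'AD'")
  if (sum(labels == "CN") < 2L || sum(labels == "AD") < 2L)
    abort("label_error", "each class needs at least 2 members")
  labels
}

#' Train the PCA + LDA atrophy-pattern classifier
#'
#' @param features numeric matrix of w-score feature vectors, one subject
#'   per row.
#' @param labels character/factor vector of `"CN"` / `"AD"`, one per row.
#' @param pca_dim explicit PCA dimension; if `NULL` (default) the smallest
#'   dimension explaining at least `var_fraction` of the variance is used,
#'   capped at `n - 2`.
#' @param var_fraction variance-explained target for the automatic PCA
#'   dimension rule (default 0.9).
#' @param ridge within-class scatter regularization, scaled as
#'   `ridge * trace(Sw) / d` on the diagonal (default 1e-6).
#' @param basis_fingerprint,model_fingerprint optional provenance digests of
#'   the spectral basis and normative model the features came through.
#' @return an object of class `atrophy_classifier`: `center` (feature mean),
#'   `rotation` (features x d orthonormal PCA axes), `explained_variance`,
#'   `lda_axis` (unit vector in PCA space), `proj_cn`, `proj_ad` (class-mean
#'   projections), `threshold` (decision midpoint), `n_cn`, `n_ad`, and the
#'   provenance fingerprints.
#' @export
train_classifier <- function(features, labels, pca_dim = NULL,
                             var_fraction = 0.9, ridge = 1e-6,
                             basis_fingerprint = NA_character_,
                             model_fingerprint = NA_character_) {
  features <- as.matrix(features)
  labels <- check_labels(labels)
  n <- nrow(features)
  p <- ncol(features)
  if (length(labels) != n)
    abort("alignment_error", "one label per feature row required")

  center <- colMeans(features)
  xc <- sweep(features, 2L, center)
  dmax <- min(n - 2L, p)
  sv <- svd(xc, nu = 0L, nv = dmax)
  ev <- sv$d^2
  evr <- ev / sum(ev)
  if (is.null(pca_dim)) {
    d <- which(cumsum(evr) >= var_fraction - 1e-12)[1L]
    if (is.na(d)) d <- dmax
    d <- min(d, dmax)
  } else {
    if (pca_dim < 1L || pca_dim > dmax)
      abort("argument_error",
            sprintf("pca_dim = %d outside [1, %d]", pca_dim, dmax))
    d <- as.integer(pca_dim)
  }
  rotation <- sv$v[, seq_len(d), drop = FALSE]
  scores <- xc %*% rotation

  is_ad <- labels == "AD"
  m_cn <- colMeans(scores[!is_ad, , drop = FALSE])
  m_ad <- colMeans(scores[is_ad, , drop = FALSE])
  sw <- crossprod(sweep(scores[!is_ad, , drop = FALSE], 2L, m_cn)) +
    crossprod(sweep(scores[is_ad, , drop = FALSE], 2L, m_ad))
  lam <- ridge * sum(diag(sw)) / d
  axis <- tryCatch(
    solve(sw + diag(lam, d), m_ad - m_cn),
    error = function(e) abort(
      "numerical_error",
      "within-class scatter is singular; increase the ridge parameter")
  )
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0)
    abort("numerical_error", "degenerate LDA axis (identical class means)")
  axis <- axis / nrm
  proj_cn <- sum(m_cn * axis)
  proj_ad <- sum(m_ad * axis)
  if (proj_ad < proj_cn) { # orientation convention: AD above CN
    axis <- -axis
    tmp <- proj_cn; proj_cn <- proj_ad; proj_ad <- tmp
  }

  structure(
    list(center = center, rotation = rotation,
         explained_variance = evr[seq_len(d)],
         lda_axis = axis, proj_cn = proj_cn, proj_ad = proj_ad,
         threshold = (proj_cn + proj_ad) / 2,
         n_cn = sum(!is_ad), n_ad = sum(is_ad),
         basis_fingerprint = basis_fingerprint,
         model_fingerprint = model_fingerprint),
    class = "atrophy_classifier"
  )
}

#' @export
print.atrophy_classifier <- function(x, ...) {
  cat(sprintf("atrophy_classifier: %d features -> %d PCA axes -> 1 LDA axis\n",
              length(x$center), ncol(x$rotation)))
  cat(sprintf("  trained on %d CN / %d AD; class-mean projections %.3f / %.3f\n",
              x$n_cn, x$n_ad, x$proj_cn, x$proj_ad))
  invisible(x)
}

#' @export
summary.atrophy_classifier <- function(object, ...) {
  cat(sprintf("PCA: %d axes, %.1f%% variance explained\n",
              ncol(object$rotation), 100 * sum(object$explained_variance)))
  cat(sprintf("LDA separation (AD - CN mean projection): %.4f\n",
              object$proj_ad - object$proj_cn))
  cat(sprintf("Decision threshold: %.4f (ties -> CN)\n", object$threshold))
  invisible(object)
}

#' Project feature vectors onto the trained LDA axis
#'
#' An affine map of the raw feature vector: centering, PCA rotation, then
#' the inner product with the discriminant axis.
#'
#' @param classifier an `atrophy_classifier`.
#' @param features numeric vector (one subject) or matrix (subjects x
#'   features).
#' @return scalar LDA coordinate(s).
#' @export
project <- function(classifier, features) {
  single <- !is.matrix(features)
  x <- if (single) matrix(features, nrow = 1L) else as.matrix(features)
  if (ncol(x) != length(classifier$center))
    abort("alignment_error",
          sprintf("feature length %d does not match training dimension %d",
                  ncol(x), length(classifier$center)))
  out <- as.numeric(sweep(x, 2L, classifier$center) %*%
                      classifier$rotation %*% classifier$lda_axis)
  out
}

#' Classify feature vectors as CN or AD
#'
#' AD iff the LDA projection exceeds the decision threshold; a projection
#' exactly on the threshold is called CN.
#'
#' @inheritParams project
#' @return character vector of `"CN"` / `"AD"`.
#' @export
classify <- function(classifier, features) {
  ifelse(project(classifier, features) > classifier$threshold, "AD", "CN")
}

#' @export
predict.atrophy_classifier <- function(object, features,
                                       type = c("class", "projection",
                                                "similarity"), ...) {
  type <- match.arg(type)
  switch(type,
         class = classify(object, features),
         projection = project(object, features),
         similarity = atrophy_similarity(object, features)$scaled)
}

#' Per-vertex discriminative weight map
#'
#' Composes the LDA axis back through the orthonormal PCA axes into feature
#' (vertex) space. The returned weights are oriented so that a positive
#' weight means cortical thinning at that vertex pushes a subject toward the
#' AD side of the discriminant (thinning lowers the w-score, so this is the
#' negated feature-space axis).
#'
#' @param classifier an `atrophy_classifier`.
#' @param basis optional `spectral_basis`; when supplied its digest is
#'   checked against the classifier's training provenance.
#' @param model optional `normative_model`, checked likewise.
#' @return numeric vector of one signed weight per vertex/feature.
#' @export
discriminative_map <- function(classifier, basis = NULL, model = NULL) {
  if (!is.null(basis) && !is.na(classifier$basis_fingerprint)) {
    if (!identical(object_fingerprint(unclass(basis)),
                   classifier$basis_fingerprint))
      abort("provenance_error",
            "spectral basis does not match the classifier's training basis")
  }
  if (!is.null(model) && !is.na(classifier$model_fingerprint)) {
    if (!identical(object_fingerprint(unclass(model)),
                   classifier$model_fingerprint))
      abort("provenance_error",
            "normative model does not match the classifier's training model")
  }
  -as.numeric(classifier$rotation %*% classifier$lda_axis)
}

stratified_folds <- function(labels, n_folds, seed) {
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  assign
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Folds are stratified by diagnosis so each test fold preserves the class
#' proportions within one subject. Inside every training fold the normative
#' model is refit on that fold's CN subjects and w-scores are recomputed for
#' both the training and test subjects before PCA/LDA training, so no
#' information leaks from test to train.
#'
#' @param thickness numeric matrix of noise-filtered thickness, one subject
#'   per row.
#' @param age,education covariate vectors.
#' @param labels `"CN"` / `"AD"` per subject; AD is the positive class.
#' @param n_folds number of folds (default 10); must not exceed the smaller
#'   class count.
#' @param seed integer seed controlling the fold assignment.
#' @param pca_dim,var_fraction,ridge forwarded to [train_classifier()].
#' @param min_train forwarded to [fit_normative()].
#' @return an object of class `cv_result` with per-fold confusion counts,
#'   aggregate `accuracy`, `sensitivity`, `specificity`, the fold
#'   assignment, and the seed.
#' @export
cross_validate <- function(thickness, age, education, labels, n_folds = 10L,
                           seed = 1L, pca_dim = NULL, var_fraction = 0.9,
                           ridge = 1e-6, min_train = 10L) {
  thickness <- as.matrix(thickness)
  labels <- check_labels(labels)
  n <- nrow(thickness)
  if (length(labels) != n || length(age) != n || length(education) != n)
    abort("alignment_error", "labels/age/education must match thickness rows")
  if (n_folds > min(table(labels)))
    abort("argument_error",
          sprintf("n_folds = %d exceeds the smaller class count (%d)",
                  n_folds, min(table(labels))))
  assign <- stratified_folds(labels, n_folds, seed)
  folds <- vector("list", n_folds)
  for (fold in seq_len(n_folds)) {
    test <- which(assign == fold)
    train <- which(assign != fold)
    cn_train <- train[labels[train] == "CN"]
    norm <- fit_normative(thickness[cn_train, , drop = FALSE],
                          age[cn_train], education[cn_train],
                          min_train = min_train)
    w_train <- compute_wscore(norm, thickness[train, , drop = FALSE],
                              age[train], education[train])
    w_test <- compute_wscore(norm, thickness[test, , drop = FALSE],
                             age[test], education[test])
    clf <- train_classifier(w_train, labels[train], pca_dim = pca_dim,
                            var_fraction = var_fraction, ridge = ridge)
    pred <- classify(clf, w_test)
    truth <- labels[test]
    folds[[fold]] <- c(
      tp = sum(pred == "AD" & truth == "AD"),
      fp = sum(pred == "AD" & truth == "CN"),
      tn = sum(pred == "CN" & truth == "CN"),
      fn = sum(pred == "CN" & truth == "AD")
    )
  }
  conf <- Reduce(`+`, folds)
  structure(
    list(folds = folds, confusion = conf,
         accuracy = (conf[["tp"]] + conf[["tn"]]) / sum(conf),
         sensitivity = conf[["tp"]] / (conf[["tp"]] + conf[["fn"]]),
         specificity = conf[["tn"]] / (conf[["tn"]] + conf[["fp"]]),
         fold_assignment = assign, n_folds = n_folds, seed = seed),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$n_folds, x$seed))
  cat(sprintf("  accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d (AD positive)\n",
              x$confusion[["tp"]], x$confusion[["fp"]],
              x$confusion[["tn"]], x$confusion[["fn"]]))
  invisible(x)
}

#' Serialize / read a trained classifier
#'
#' @param classifier an `atrophy_classifier`.
#' @param path file path.
#' @return `path` (write) or the classifier (read).
#' @export
write_classifier <- function(classifier, path) {
  saveRDS(classifier, path, version = 2)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  clf <- readRDS(path)
  if (!inherits(clf, "atrophy_classifier"))
    abort("format_error", sprintf("%s does not contain an atrophy_classifier",
                                  path))
  clf
}
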