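# AD-specific atrophy-similarity score and the per-subject Z-score map.
#
# The raw measure is the subject's signed coordinate on the trained LDA
# axis. Because a literal distance to the AD group mean would decrease as a
# subject becomes more AD-like, the score is reported as the affinely
# anchored coordinate: the CN training mean maps to 0 and the AD training
# mean to 100, with no clipping (patterns more extreme than the AD mean
# legitimately score above 100).

#' AD-specific atrophy similarity of a subject
#'
#' @param classifier an `atrophy_classifier`.
#' @param feature w-score feature vector (or matrix, one subject per row).
#' @param subject_id,visit_time optional metadata echoed into the result.
#' @return a data frame with columns `subject_id`, `visit_time`, `raw`
#'   (signed LDA coordinate) and `scaled` (anchored score; 0 = CN training
#'   mean, 100 = AD training mean).
#' @export
atrophy_similarity <- function(classifier, feature,
                               subject_id = NA_character_, visit_time = 0) {
  sep <- classifier$proj_ad - classifier$proj_cn
  if (!is.finite(sep) || sep <= 0)
    abort("configuration_error",
          "degenerate classifier: CN and AD mean projections coincide")
  raw <- project(classifier, feature)
  data.frame(
    subject_id = rep_len(subject_id, length(raw)),
    visit_time = rep_len(visit_time, length(raw)),
    raw = raw,
    scaled = 100 * (raw - classifier$proj_cn) / sep
  )
}

#' Per-subject Z-score map of AD-like atrophy
#'
#' Decomposes a subject's LDA projection into per-vertex contributions
#' (feature-space discriminant weight times the subject's w-score, signed so
#' that positive means AD-like thinning at that vertex) and standardizes the
#' contribution field across vertices to mean 0, SD 1.
#'
#' @param classifier an `atrophy_classifier`.
#' @param feature w-score vector for one subject.
#' @param basis,model optional provenance objects, checked as in
#'   [discriminative_map()].
#' @return numeric Z-score per vertex (mean 0, SD 1).
#' @export
zscore_map <- function(classifier, feature, basis = NULL, model = NULL) {
  weights <- -discriminative_map(classifier, basis, model) # raw LDA axis
  feature <- as.numeric(feature)
  if (length(feature) != length(weights))
    abort("alignment_error",
          sprintf("feature length %d does not match classifier dimension %d",
                  length(feature), length(weights)))
  contrib <- weights * feature
  s <- stats::sd(contrib)
  if (!is.finite(s) || s == 0)
    abort("degenerate_error",
          "constant per-vertex contribution field; Z map undefined")
  (contrib - mean(contrib)) / s
}
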