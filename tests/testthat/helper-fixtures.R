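# Shared fixtures, memoised per test session (see cached() in
# helper-oracles.R). All fixtures are generated in code; no files ship with
# the package.

fix_sphere <- function(s) cached(paste0("sphere", s), make_icosphere(s))

# small cohort with the default (moderate) effect size
fix_cohort <- function() cached("cohort", {
  generate_cohort(cohort_spec(n_cn = 60, n_ad = 60, seed = 7))
})

# strongly separated cohort: deep patch, tight severity spread
fix_strong_cohort <- function() cached("strong_cohort", {
  generate_cohort(cohort_spec(n_cn = 100, n_ad = 100, patch_depth = 1.0,
                              severity_sdlog = 0.1, seed = 11))
})

fix_filtered <- function(cohort_fn = fix_cohort, key = "filtered") {
  cached(key, {
    co <- cohort_fn()
    basis <- compute_basis(co$mesh, 40)
    list(cohort = co, basis = basis,
         filtered = lowpass_filter_matrix(basis, co$thickness, 40))
  })
}

fix_strong_filtered <- function() fix_filtered(fix_strong_cohort,
                                               "strong_filtered")

# trained classifier on the strong cohort (normative fit on CN only)
fix_trained <- function() cached("trained", {
  fs <- fix_strong_filtered()
  cov <- fs$cohort$covariates
  cn <- cov$diagnosis == "CN"
  nm <- fit_normative(fs$filtered[cn, ], cov$age[cn], cov$education[cn])
  w <- compute_wscore(nm, fs$filtered, cov$age, cov$education)
  clf <- train_classifier(w, cov$diagnosis)
  list(cohort = fs$cohort, basis = fs$basis, filtered = fs$filtered,
       normative = nm, wscores = w, classifier = clf)
})
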