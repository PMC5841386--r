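# PCA + two-class LDA training, projection, classification,
# cross-validation and the discriminative map.

test_that("isotropic clusters give an LDA axis parallel to the mean difference", {
  with_seed(31, {
    x <- rbind(matrix(rnorm(200 * 2, 0, 1), 200),
               sweep(matrix(rnorm(200 * 2, 0, 1), 200), 2, c(3, 1), "+"))
  })
  lab <- rep(c("CN", "AD"), each = 200)
  clf <- train_classifier(x, lab, pca_dim = 2)
  mu_diff <- colMeans(x[lab == "AD", ]) - colMeans(x[lab == "CN", ])
  axis_feat <- as.numeric(clf$rotation %*% clf$lda_axis)
  cosang <- sum(axis_feat * mu_diff) /
    sqrt(sum(axis_feat^2) * sum(mu_diff^2))
  # equal isotropic covariances: direction within ~3 degrees of mu_AD - mu_CN
  expect_gt(cosang, cos(3 * pi / 180))
})

test_that("pipeline projections match the dense textbook LDA oracle", {
  with_seed(32, {
    x <- matrix(rnorm(30 * 50), 30)
    lab <- rep(c("CN", "AD"), 15)
    x[lab == "AD", 1:5] <- x[lab == "AD", 1:5] + 1
  })
  clf <- train_classifier(x, lab, pca_dim = 10, ridge = 0)
  al <- align_projections(project(clf, x), dense_lda_oracle(x, lab, 10))
  expect_lt(max(abs(al$a - al$b)), 1e-6)
})

test_that("projection is affine and anchored at the class means", {
  tr <- fix_trained()
  clf <- tr$classifier
  w <- tr$wscores
  lab <- tr$cohort$covariates$diagnosis
  m_cn <- colMeans(w[lab == "CN", ])
  m_ad <- colMeans(w[lab == "AD", ])
  expect_equal(project(clf, m_cn), clf$proj_cn, tolerance = 1e-8)
  expect_equal(project(clf, m_ad), clf$proj_ad, tolerance = 1e-8)
  expect_equal(project(clf, (m_cn + m_ad) / 2),
               (clf$proj_cn + clf$proj_ad) / 2, tolerance = 1e-8)
  # affinity on random convex combinations
  with_seed(33, {
    for (i in 1:5) {
      a <- runif(1)
      x <- w[sample(nrow(w), 1), ]
      y <- w[sample(nrow(w), 1), ]
      expect_equal(project(clf, a * x + (1 - a) * y),
                   a * project(clf, x) + (1 - a) * project(clf, y),
                   tolerance = 1e-8)
    }
  })
  expect_error(project(clf, w[, -1]), class = "atroscore_alignment_error")
})

test_that("classification is AD above the threshold with ties called CN", {
  tr <- fix_trained()
  clf <- tr$classifier
  w <- tr$wscores
  lab <- tr$cohort$covariates$diagnosis
  m_cn <- colMeans(w[lab == "CN", ])
  m_ad <- colMeans(w[lab == "AD", ])
  expect_identical(classify(clf, m_ad), "AD")
  expect_identical(classify(clf, m_cn), "CN")
  expect_identical(predict(clf, rbind(m_cn, m_ad)), c("CN", "AD"))

  # exact tie: symmetric classes make the midpoint projection exactly the
  # threshold, and the documented rule calls it CN
  xs <- rbind(c(0, 0), c(0, 1), c(2, 0), c(2, 1))
  cs <- train_classifier(xs, c("CN", "CN", "AD", "AD"), pca_dim = 2)
  expect_identical(project(cs, cs$center), cs$threshold)
  expect_identical(classify(cs, cs$center), "CN")
})

test_that("degenerate label sets are refused", {
  x <- matrix(rnorm(20 * 4), 20)
  expect_error(train_classifier(x, rep("AD", 20)),
               class = "atroscore_label_error")
  expect_error(train_classifier(x, c("CN", rep("AD", 19))),
               class = "atroscore_label_error")
  expect_error(train_classifier(x, rep(c("CN", "AD"), 10), pca_dim = 30),
               class = "atroscore_argument_error")
})

test_that("stratified folds balance classes and partition the sample", {
  lab <- rep(c("CN", "AD"), each = 10)
  thick <- with_seed(34, matrix(rnorm(20 * 30, 2.5, 0.1), 20))
  cv <- cross_validate(thick, runif(20, 60, 80), runif(20, 8, 18), lab,
                       n_folds = 10, seed = 2, min_train = 5)
  sizes <- table(cv$fold_assignment)
  expect_true(all(sizes == 2)) # one CN + one AD per test fold
  for (f in 1:10)
    expect_setequal(lab[cv$fold_assignment == f], c("CN", "AD"))
  expect_error(
    cross_validate(thick, runif(20, 60, 80), runif(20, 8, 18), lab,
                   n_folds = 11, min_train = 5),
    class = "atroscore_argument_error")
})

test_that("cross-validation is deterministic given the seed", {
  fs <- fix_filtered()
  cov <- fs$cohort$covariates
  cv1 <- cross_validate(fs$filtered, cov$age, cov$education, cov$diagnosis,
                        seed = 42)
  cv2 <- cross_validate(fs$filtered, cov$age, cov$education, cov$diagnosis,
                        seed = 42)
  expect_identical(cv1, cv2)
  conf <- cv1$confusion
  expect_equal(cv1$accuracy, (conf[["tp"]] + conf[["tn"]]) / sum(conf))
  expect_equal(cv1$sensitivity, conf[["tp"]] / (conf[["tp"]] + conf[["fn"]]))
  expect_equal(cv1$specificity, conf[["tn"]] / (conf[["tn"]] + conf[["fp"]]))
})

test_that("cross-validated accuracy grows with the simulated effect size", {
  accs <- vapply(c(0, 0.35, 1.0), function(depth) {
    co <- generate_cohort(cohort_spec(n_cn = 40, n_ad = 40,
                                      patch_depth = depth,
                                      severity_sdlog = 0.1, seed = 35))
    basis <- co$basis
    filt <- lowpass_filter_matrix(basis, co$thickness, basis$k)
    cross_validate(filt, co$covariates$age, co$covariates$education,
                   co$covariates$diagnosis, n_folds = 5, seed = 1)$accuracy
  }, numeric(1))
  expect_lt(accs[1], 0.7)   # null: near chance
  expect_gt(accs[3], 0.95)  # strong effect: near perfect
  expect_gte(accs[3], accs[2] - 0.05)
  expect_gte(accs[2], accs[1] - 0.05)
})

test_that("discriminative map has unit norm and flags mismatched provenance", {
  tr <- fix_trained()
  clf <- tr$classifier
  dm <- discriminative_map(clf)
  expect_length(dm, ncol(tr$wscores))
  # back-projection through orthonormal PCA axes preserves the unit norm
  expect_equal(sqrt(sum(dm^2)), 1, tolerance = 1e-8)

  clf2 <- train_classifier(
    tr$wscores, tr$cohort$covariates$diagnosis,
    basis_fingerprint = object_fingerprint(unclass(tr$basis)),
    model_fingerprint = object_fingerprint(unclass(tr$normative)))
  expect_silent(discriminative_map(clf2, tr$basis, tr$normative))
  other_basis <- compute_basis(fix_sphere(1), 5)
  expect_error(discriminative_map(clf2, other_basis),
               class = "atroscore_provenance_error")
})

test_that("the map recovers the simulated atrophy patch and nulls stay flat", {
  tr <- fix_trained()
  dm <- discriminative_map(tr$classifier)
  truth <- which(tr$cohort$truth$patch_mask)
  top <- order(abs(dm), decreasing = TRUE)[seq_len(round(0.1 * length(dm)))]
  dice <- 2 * length(intersect(top, truth)) / (length(top) + length(truth))
  expect_gt(dice, 0.5)
  # patch weights point the right way: thinning there pushes toward AD
  expect_gt(mean(dm[truth]), 0)

  # identical class distributions: weights indistinguishable from the
  # permutation distribution of the same statistic
  fs <- fix_filtered()
  cov <- fs$cohort$covariates
  cn <- cov$diagnosis == "CN"
  nm <- fit_normative(fs$filtered[cn, ], cov$age[cn], cov$education[cn])
  w_cn <- compute_wscore(nm, fs$filtered[cn, ], cov$age[cn],
                         cov$education[cn])
  lab_half <- rep(c("CN", "AD"), length.out = nrow(w_cn)) # arbitrary split
  obs <- max(abs(discriminative_map(train_classifier(w_cn, lab_half))))
  perm <- vapply(1:19, function(s) {
    pl <- with_seed(600 + s, sample(lab_half))
    max(abs(discriminative_map(train_classifier(w_cn, pl))))
  }, numeric(1))
  expect_lte(sum(perm < obs), 18) # observed max not an outlier vs permutations
})
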