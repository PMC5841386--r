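# Independent oracles used by the tests. These deliberately use dense,
# textbook formulations (not the package's code paths) so agreement is
# evidence, not tautology.

# Dense two-class Fisher LDA in PCA space: eig(Sw^-1 Sb). Returns the
# projection of every subject onto the leading discriminant, up to sign and
# scale.
dense_lda_oracle <- function(features, labels, d) {
  x <- as.matrix(features)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  # PCA axes from the eigendecomposition of the covariance matrix
  cv <- crossprod(xc) / (nrow(x) - 1)
  ev <- eigen(cv, symmetric = TRUE)
  rot <- ev$vectors[, seq_len(d), drop = FALSE]
  z <- xc %*% rot
  is_ad <- labels == "AD"
  m1 <- colMeans(z[!is_ad, , drop = FALSE])
  m2 <- colMeans(z[is_ad, , drop = FALSE])
  sw <- crossprod(sweep(z[!is_ad, , drop = FALSE], 2L, m1)) +
    crossprod(sweep(z[is_ad, , drop = FALSE], 2L, m2))
  sb <- outer(m2 - m1, m2 - m1) *
    (sum(!is_ad) * sum(is_ad) / nrow(x)) # scale irrelevant for the axis
  eg <- eigen(solve(sw) %*% sb)
  axis <- Re(eg$vectors[, which.max(Re(eg$values))])
  as.numeric(z %*% axis)
}

# center + unit-norm + sign-align two projection vectors for comparison
align_projections <- function(a, b) {
  a <- (a - mean(a)) / sqrt(sum((a - mean(a))^2))
  b <- (b - mean(b)) / sqrt(sum((b - mean(b))^2))
  if (sum(a * b) < 0) b <- -b
  list(a = a, b = b)
}

# Random-intercept REML by profiled likelihood over the variance ratio
# theta = var_u / var_e, dense GLS per candidate theta. Independent of lme4.
profile_reml_oracle <- function(d, formula_x) {
  X <- stats::model.matrix(formula_x, d)
  y <- d$outcome_value
  subj <- factor(d$subject_id)
  Z <- stats::model.matrix(~ subj - 1)
  n <- length(y)
  p <- ncol(X)
  crit <- function(theta) {
    V <- diag(n) + theta * tcrossprod(Z)
    ch <- chol(V)
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    XtViX <- crossprod(X, Vi_X)
    beta <- solve(XtViX, crossprod(X, Vi_y))
    r <- y - X %*% beta
    Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
    logdetV <- 2 * sum(log(diag(ch)))
    logdetX <- determinant(XtViX, logarithm = TRUE)$modulus
    as.numeric(logdetV + logdetX + (n - p) * log(crossprod(r, Vi_r)))
  }
  opt <- stats::optimize(crit, c(1e-8, 1e3))
  theta <- opt$minimum
  V <- diag(n) + theta * tcrossprod(Z)
  ch <- chol(V)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(X, Vi_y))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  s2e <- as.numeric(crossprod(r, Vi_r)) / (n - p)
  list(beta = as.numeric(beta), terms = colnames(X),
       var_e = s2e, var_u = theta * s2e)
}

# simple per-session memo cache for expensive fixtures
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}
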