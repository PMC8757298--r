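# REML machinery for the polygenic linear mixed model
#   y = X beta + g + e,  g ~ N(0, sigma2_g * K),  e ~ N(0, sigma2_e * I)
# One eigendecomposition of K per (kinship, sample subset); a 1-D REML
# optimization over the variance ratio per phenotype.

# Eigen-prepare a kinship matrix.  Eigenvalues are rescaled so the matrix
# has unit mean diagonal, which puts the variance ratio h = s2g/(s2g+s2e)
# on the heritability scale (a unit polygenic component contributes unit
# trait variance).  A (near-)zero matrix degenerates to "no kinship".
kinship_eigen <- function(K) {
  tr <- sum(diag(K))
  n <- nrow(K)
  if (tr < 1e-12 * n) return(structure(list(U = NULL, d = NULL, n = n),
                                       class = "kinship_eigen"))
  eg <- eigen(K * (n / tr), symmetric = TRUE)
  structure(list(U = eg$vectors, d = pmax(eg$values, 0), n = n),
            class = "kinship_eigen")
}

# Rotate columns of A into the kinship eigenbasis (identity if no kinship).
rotate_eig <- function(eigK, A) {
  if (is.null(eigK$U)) A else crossprod(eigK$U, A)
}

#' Fit the null polygenic model by REML
#'
#' Estimates the polygenic and residual variance components of
#' `y = X beta + g + e` with `g ~ N(0, sigma2_g K)` via one
#' eigendecomposition of the kinship and a bounded 1-D optimization of the
#' REML criterion over the log variance ratio (tolerance 1e-8).  The
#' kinship is internally normalized to unit mean diagonal, so
#' `sigma2_g / (sigma2_g + sigma2_e)` is directly the heritability-scale
#' ratio.
#'
#' @param y Numeric phenotype vector.
#' @param kinship Kinship matrix, a prepared `kinship_eigen` object, or
#'   `NULL`/zero matrix for no polygenic term.
#' @param addcovar Optional covariate matrix/data-frame columns (an
#'   intercept is always included).
#' @return Object of class `null_fit`: `hsq` (the ratio), `sigma2_g`,
#'   `sigma2_e`, `loglik` (REML, up to a constant), `beta`, `n`.
#' @export
fit_null <- function(y, kinship = NULL, addcovar = NULL) {
  n <- length(y)
  X <- build_covar(addcovar, n)
  if (n < ncol(X) + 2L) stopf("need n >= number of fixed effects + 2")
  check_full_rank(X)
  eigK <- as_kinship_eigen(kinship, n)
  fit <- reml_fit(y, X, eigK)
  structure(list(hsq = fit$h, sigma2_g = fit$h * fit$sigma2,
                 sigma2_e = (1 - fit$h) * fit$sigma2,
                 sigma2 = fit$sigma2, loglik = fit$loglik,
                 beta = fit$beta, n = n, eigK = eigK, weights = fit$w),
            class = "null_fit")
}

#' @export
print.null_fit <- function(x, ...) {
  cat(sprintf("Polygenic null fit (REML): n = %d\n", x$n))
  cat(sprintf("  sigma2_g = %.4g, sigma2_e = %.4g, ratio h = %.3f\n",
              x$sigma2_g, x$sigma2_e, x$hsq))
  invisible(x)
}

as_kinship_eigen <- function(kinship, n) {
  if (is.null(kinship))
    return(structure(list(U = NULL, d = NULL, n = n), class = "kinship_eigen"))
  if (inherits(kinship, "kinship_eigen")) return(kinship)
  if (inherits(kinship, "kinship_set")) return(kinship_eigen(kinship$full))
  kinship_eigen(as.matrix(kinship))
}

build_covar <- function(addcovar, n) {
  if (is.null(addcovar)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  A <- as.matrix(addcovar)
  if (nrow(A) != n) stopf("covariates have %d rows, phenotype %d", nrow(A), n)
  if (is.null(colnames(A))) colnames(A) <- paste0("covar", seq_len(ncol(A)))
  cbind(intercept = 1, A)
}

check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stopf("singular fixed-effect design; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# Core REML fit: profile criterion over h = s2g/(s2g+s2e).
# Returns h, total variance sigma2, REML loglik (up to constant), GLS beta,
# and the rotated-space variance weights w = h*d + (1-h).
reml_fit <- function(y, X, eigK) {
  n <- length(y); p <- ncol(X)
  yr <- as.vector(rotate_eig(eigK, matrix(y)))
  Xr <- rotate_eig(eigK, X)
  if (stats::var(y) < 1e-14 * max(1, mean(y)^2)) {
    # constant phenotype: degenerate but well-defined
    return(list(h = 0, sigma2 = 0, loglik = NA_real_,
                beta = c(mean(y), rep(0, p - 1L)), w = rep(1, n)))
  }
  if (is.null(eigK$U)) {
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(max(rss, 1e-300)))
    return(list(h = 0, sigma2 = s2, loglik = ll,
                beta = fit$coefficients, w = rep(1, n)))
  }
  d <- eigK$d
  crit <- function(h) {
    w <- h * d + (1 - h)
    sw <- 1 / sqrt(w)
    fit <- stats::lm.fit(Xr * sw, yr * sw)
    rss <- max(sum(fit$residuals^2), 1e-300)
    qrX <- fit$qr
    ldXX <- 2 * sum(log(abs(diag(qrX$qr)[seq_len(qrX$rank)])))
    0.5 * ((n - p) * log(rss) + sum(log(w)) + ldXX)
  }
  # optimize over logit(h); compare with the h = 0 boundary
  opt <- stats::optimize(function(t) crit(stats::plogis(t)),
                         interval = c(-25, 25), tol = 1e-8)
  h <- stats::plogis(opt$minimum)
  if (crit(0) <= opt$objective) h <- 0
  w <- h * d + (1 - h)
  sw <- 1 / sqrt(w)
  fit <- stats::lm.fit(Xr * sw, yr * sw)
  rss <- sum(fit$residuals^2)
  list(h = h, sigma2 = rss / (n - p), loglik = -crit(h),
       beta = fit$coefficients, w = w)
}
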