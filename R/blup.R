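# BLUP founder allele effects at a single marker: allele dosages as a
# random effect (ridge-like shrinkage with REML-estimated variance), on
# top of the polygenic whitening used by the scan.

#' BLUP founder effects at one marker
#'
#' Fits `y = X beta + Z u + g + e` where `Z` is the 8-column founder
#' dosage block at the marker and `u ~ N(0, sigma2_u I)` is a random
#' founder effect.  The polygenic term is absorbed by whitening with the
#' REML null variance components (as in [qtl_scan()]); `sigma2_u` is then
#' estimated by a 1-D REML optimization and the founder effects are the
#' BLUPs, shrunken relative to the least-squares solution on the same
#' whitened design.
#'
#' @param probs Allele-probability tensor.
#' @param marker Marker id (must exist in `probs`).
#' @param pheno Phenotype vector.
#' @param kinship Kinship matrix / `kinship_set` (LOCO matrix of the
#'   marker's chromosome used when a set with `loco` and a map are
#'   available) or `NULL`.
#' @param addcovar Optional additive covariates.
#' @param map Marker map (needed to pick the LOCO matrix).
#' @return Object of class `founder_blup`: `effects` (8 named founder
#'   coefficients, trait units per dosage), `intercept`, `marker`,
#'   `lambda` (variance ratio sigma2_u/sigma2_e).
#' @export
blup_effects <- function(probs, marker, pheno, kinship = NULL,
                         addcovar = NULL, map = attr(probs, "map")) {
  mi <- match(marker, dimnames(probs)[[2]])
  if (is.na(mi)) stopf("marker '%s' not found", marker)
  n <- dim(probs)[1]
  Z <- probs[, mi, ]
  if (sum(colSums(Z) > 1e-8) < 2L)
    stopf("fewer than 2 founders represented at marker '%s'", marker)
  X0 <- build_covar(addcovar, n)
  eigK <- pick_marker_eigen(kinship, map, marker, n)
  nf <- reml_fit(pheno, X0, eigK)
  sw <- 1 / sqrt(nf$w)
  whiten <- if (is.null(eigK$U)) function(A) A * sw else
    function(A) crossprod(eigK$U, A) * sw
  Xw <- whiten(X0)
  Zw <- whiten(Z)
  yw <- as.vector(whiten(matrix(pheno)))

  p <- ncol(Xw)
  G <- crossprod(Zw)
  ZtX <- crossprod(Zw, Xw)
  Zty <- as.vector(crossprod(Zw, yw))
  # V = I + lambda * Zw Zw'; Woodbury through the 8x8 core
  core <- function(lambda) solve(diag(8) / lambda + G)
  vinv_mult <- function(Cm, A) A - Zw %*% (Cm %*% crossprod(Zw, A))
  crit <- function(loglam) {
    lambda <- exp(loglam)
    Cm <- core(lambda)
    XtViX <- crossprod(Xw, vinv_mult(Cm, Xw))
    XtViy <- crossprod(Xw, vinv_mult(Cm, matrix(yw)))
    beta <- solve(XtViX, XtViy)
    r <- yw - as.vector(Xw %*% beta)
    rViR <- sum(r * as.vector(vinv_mult(Cm, matrix(r))))
    ldV <- determinant(diag(8) + lambda * G, logarithm = TRUE)$modulus
    ldX <- determinant(XtViX, logarithm = TRUE)$modulus
    0.5 * ((n - p) * log(max(rViR, 1e-300)) + as.numeric(ldV) + as.numeric(ldX))
  }
  opt <- stats::optimize(crit, interval = c(-20, 20), tol = 1e-8)
  lambda <- exp(opt$minimum)
  Cm <- core(lambda)
  XtViX <- crossprod(Xw, vinv_mult(Cm, Xw))
  XtViy <- crossprod(Xw, vinv_mult(Cm, matrix(yw)))
  beta <- as.vector(solve(XtViX, XtViy))
  r <- yw - as.vector(Xw %*% beta)
  u <- lambda * as.vector(crossprod(Zw, vinv_mult(Cm, matrix(r))))
  names(u) <- names(do_founders)
  structure(list(effects = u, intercept = beta[1], beta = beta,
                 marker = marker, lambda = lambda),
            class = "founder_blup")
}

pick_marker_eigen <- function(kinship, map, marker, n) {
  if (is.null(kinship))
    return(structure(list(U = NULL, d = NULL, n = n), class = "kinship_eigen"))
  if (inherits(kinship, "kinship_set") && !is.null(kinship$loco) &&
      !is.null(map)) {
    cc <- map$chrom[match(marker, map$marker)]
    if (!is.na(cc) && cc %in% names(kinship$loco))
      return(kinship_eigen(kinship$loco[[cc]]))
  }
  as_kinship_eigen(kinship, n)
}

#' @export
print.founder_blup <- function(x, ...) {
  cat(sprintf("BLUP founder effects at %s (lambda = %.3g)\n", x$marker, x$lambda))
  print(round(x$effects, 4))
  invisible(x)
}

#' Estimate narrow-sense heritability
#'
#' `h2 = sigma2_g / (sigma2_g + sigma2_e)` from the REML null fit with the
#' full (non-LOCO) kinship matrix, normalized to unit mean diagonal.
#'
#' @param pheno Phenotype vector or matrix (individuals x phenotypes).
#' @param kinship Full kinship matrix, `kinship_set`, or prepared
#'   `kinship_eigen`.
#' @param addcovar Optional additive covariates.
#' @return Named numeric vector of h2 estimates in `[0, 1]`.
#' @export
est_herit <- function(pheno, kinship, addcovar = NULL) {
  pheno <- as_pheno_matrix(pheno)
  eigK <- as_kinship_eigen(kinship, nrow(pheno))
  X <- build_covar(addcovar, nrow(pheno))
  check_full_rank(X)
  vapply(seq_len(ncol(pheno)), function(j) {
    reml_fit(pheno[, j], X, eigK)$h
  }, numeric(1)) |> stats::setNames(colnames(pheno))
}
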