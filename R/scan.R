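# Linear mixed-model genome scan over founder allele probabilities.

#' Genome scan with a linear mixed model over founder allele probabilities
#'
#' For each phenotype and each chromosome, the polygenic null model
#' (intercept + additive covariates, LOCO kinship) is fit once by REML;
#' the variance components are then held fixed across that chromosome's
#' markers and the marker fit is a generalized least-squares comparison in
#' the whitened space: `LOD = (n/2) * log10(RSS0 / RSS1)`.
#'
#' The additive model compares covariates + the 8 founder dosages (cell
#' means coding: the dosage block spans the intercept) against covariates
#' only.  The interactive model additionally includes dosage-by-covariate
#' products in the full model, against the same covariates-only null.
#' Diet-subset scans are ordinary additive scans on the subsetted inputs
#' with no diet covariate.
#'
#' @param probs Allele-probability tensor (individuals x markers x 8).
#' @param pheno Numeric vector or matrix (individuals x phenotypes).
#' @param kinship A [calc_kinship()] `kinship_set` (LOCO matrices used per
#'   chromosome), a single kinship matrix (used for every chromosome), or
#'   `NULL` for a plain Haley-Knott regression scan.
#' @param addcovar Optional additive covariates (matrix/data frame, no
#'   intercept column).
#' @param intcovar Optional interactive covariates (subset of the additive
#'   covariates); supplying them switches to the interactive model.
#' @param map Marker map; defaults to the `"map"` attribute of `probs`.
#' @param model Model tag stored on the result (defaults to "additive" or
#'   "interactive" as implied by `intcovar`).
#' @return Object of class `qtl_scan`: `lod` (markers x phenotypes),
#'   `map`, `model`, `hsq` (phenotypes x chromosomes null variance-ratio
#'   estimates), `n`.
#' @export
qtl_scan <- function(probs, pheno, kinship = NULL, addcovar = NULL,
                     intcovar = NULL, map = attr(probs, "map"),
                     model = NULL) {
  if (is.null(map)) stopf("no marker map supplied or attached to `probs`")
  pheno <- as_pheno_matrix(pheno)
  n <- dim(probs)[1]
  if (nrow(pheno) != n) stopf("pheno rows (%d) != individuals in probs (%d)",
                              nrow(pheno), n)
  if (!is.null(intcovar)) {
    intcovar <- as.matrix(intcovar)
    if (is.null(addcovar)) stopf("interactive covariates must be a subset of additive covariates")
  }
  model <- model %||% (if (is.null(intcovar)) "additive" else "interactive")
  X0 <- build_covar(addcovar, n)
  check_full_rank(X0)
  chroms <- unique(map$chrom)
  eigs <- loco_eigens(kinship, map, n)

  lod <- matrix(NA_real_, nrow(map), ncol(pheno),
                dimnames = list(map$marker, colnames(pheno)))
  hsq <- matrix(NA_real_, ncol(pheno), length(chroms),
                dimnames = list(colnames(pheno), chroms))
  for (ph in seq_len(ncol(pheno))) {
    y <- pheno[, ph]
    if (stats::var(y) < 1e-14 * max(1, mean(y)^2)) {
      warnf("phenotype '%s' is constant; LOD set to 0", colnames(pheno)[ph])
      lod[, ph] <- 0
      hsq[ph, ] <- 0
      next
    }
    for (cc in chroms) {
      idx <- which(map$chrom == cc)
      ctx <- chrom_scan_ctx(probs[, idx, , drop = FALSE], y, X0,
                            eigs[[cc]], intcovar)
      lod[idx, ph] <- ctx$lod_fun(y)
      hsq[ph, cc] <- ctx$hsq
    }
  }
  structure(list(lod = lod, map = map, model = model, hsq = hsq, n = n),
            class = "qtl_scan")
}

as_pheno_matrix <- function(pheno) {
  if (is.null(dim(pheno))) {
    pheno <- matrix(pheno, ncol = 1, dimnames = list(names(pheno), "pheno"))
  } else {
    pheno <- as.matrix(pheno)
    if (is.null(colnames(pheno)))
      colnames(pheno) <- paste0("pheno", seq_len(ncol(pheno)))
  }
  pheno
}

# One eigen-prepared kinship per chromosome (LOCO when available).
loco_eigens <- function(kinship, map, n) {
  chroms <- unique(map$chrom)
  if (is.null(kinship)) {
    none <- structure(list(U = NULL, d = NULL, n = n), class = "kinship_eigen")
    return(stats::setNames(rep(list(none), length(chroms)), chroms))
  }
  if (inherits(kinship, "kinship_set") && !is.null(kinship$loco)) {
    miss <- setdiff(chroms, names(kinship$loco))
    if (length(miss) > 0) stopf("no LOCO kinship for chromosome(s) %s",
                                paste(miss, collapse = ", "))
    return(lapply(stats::setNames(chroms, chroms),
                  function(cc) kinship_eigen(kinship$loco[[cc]])))
  }
  K <- if (inherits(kinship, "kinship_set")) kinship$full else as.matrix(kinship)
  eg <- kinship_eigen(K)
  stats::setNames(rep(list(eg), length(chroms)), chroms)
}

# Build the per-(phenotype, chromosome) scan context: null REML fit,
# whitening, QR of the whitened covariates, and orthonormal bases of the
# whitened, covariate-residualized marker blocks.  `lod_fun` evaluates the
# LOD curve for any phenotype vector under the SAME variance components
# (used for the observed scan and, held fixed, for permutation scans).
chrom_scan_ctx <- function(probs_c, y, X0, eigK, intcovar = NULL) {
  n <- length(y)
  mc <- dim(probs_c)[2]
  nf <- reml_fit(y, X0, eigK)
  sw <- 1 / sqrt(nf$w)
  whiten <- if (is.null(eigK$U)) {
    function(A) A * sw
  } else {
    function(A) crossprod(eigK$U, A) * sw
  }
  X0w <- whiten(X0)
  q0 <- qr(X0w)
  Q0 <- qr.Q(q0)[, seq_len(q0$rank), drop = FALSE]

  qs <- vector("list", mc)
  for (m in seq_len(mc)) {
    Z <- probs_c[, m, ]
    if (!is.null(intcovar)) {
      for (j in seq_len(ncol(intcovar))) Z <- cbind(Z, probs_c[, m, ] * intcovar[, j])
    }
    Zw <- whiten(Z)
    Zr <- Zw - Q0 %*% crossprod(Q0, Zw)
    # orthonormal basis via SVD: pivoted QR is not reliably rank-revealing
    # for the doubly-degenerate dosage blocks (columns sum to the intercept)
    sv <- svd(Zr, nv = 0)
    r <- sum(sv$d > sv$d[1] * 1e-8)
    qs[[m]] <- if (r > 0) sv$u[, seq_len(r), drop = FALSE] else
      matrix(0, n, 0)
  }
  bigQ <- do.call(cbind, qs)
  grp <- rep(seq_len(mc), vapply(qs, ncol, integer(1)))

  lod_fun <- function(yy) {
    yw <- whiten(matrix(yy))
    yr <- yw - Q0 %*% crossprod(Q0, yw)
    rss0 <- sum(yr^2)
    if (rss0 <= 0) return(rep(0, mc))
    b2 <- as.vector(crossprod(bigQ, yr))^2
    expl <- rep(0, mc)
    if (length(b2) > 0) {
      sums <- rowsum(b2, grp)
      expl[as.integer(rownames(sums))] <- sums[, 1]
    }
    rss1 <- pmax(rss0 - expl, rss0 * 1e-30)
    pmax(n / 2 * log10(rss0 / rss1), 0)
  }
  list(lod_fun = lod_fun, hsq = nf$h, nf = nf)
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat(sprintf("Mixed-model genome scan (%s model)\n", x$model))
  cat(sprintf("  %d markers x %d phenotypes, n = %d individuals\n",
              nrow(x$lod), ncol(x$lod), x$n))
  cat(sprintf("  max LOD = %.2f\n", max(x$lod)))
  invisible(x)
}

#' @export
summary.qtl_scan <- function(object, ...) {
  top <- apply(object$lod, 2, which.max)
  out <- data.frame(
    phenotype = colnames(object$lod),
    marker = object$map$marker[top],
    chrom = object$map$chrom[top],
    pos_mb = object$map$pos_mb[top],
    lod = object$lod[cbind(top, seq_along(top))],
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(-out$lod), ]
}

#' Plot LOD curves from a genome scan
#'
#' @param x A `qtl_scan` object.
#' @param phenotype Column name or index to plot (default: first).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.qtl_scan <- function(x, phenotype = 1, ...) {
  lodv <- x$lod[, phenotype]
  chroms <- unique(x$map$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(cc)
    max(x$map$pos_mb[x$map$chrom == cc]), numeric(1))))
  gx <- x$map$pos_mb + offs[match(x$map$chrom, chroms)]
  graphics::plot(gx, lodv, type = "n", xlab = "Position (Mb, concatenated)",
                 ylab = "LOD", ...)
  for (cc in chroms) {
    idx <- x$map$chrom == cc
    graphics::lines(gx[idx], lodv[idx])
  }
  invisible(x)
}

#' Genome-wide maximum LOD per phenotype
#'
#' @param scan A `qtl_scan` object.
#' @return Named numeric vector.
#' @export
max_lod <- function(scan) {
  stopifnot(inherits(scan, "qtl_scan"))
  apply(scan$lod, 2, max)
}
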