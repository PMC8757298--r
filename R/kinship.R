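# Kinship from founder allele probabilities, full and leave-one-chromosome-out.

#' Kinship matrices from an allele-probability tensor
#'
#' The similarity between individuals i and j over a marker set is the
#' average allele-probability inner product,
#' `K_ij = (1/M) * sum_m sum_f p_imf * p_jmf`.  The leave-one-chromosome-out
#' (LOCO) matrix for chromosome c uses all markers except those on c, so
#' that the polygenic term in a scan on c is not contaminated by the tested
#' locus.
#'
#' @param probs Allele-probability tensor (individuals x markers x 8).
#' @param map Marker map (`marker`, `chrom`, `pos_mb`); defaults to the
#'   `"map"` attribute of `probs`.
#' @param loco Compute per-chromosome LOCO matrices as well?
#' @return Object of class `kinship_set`: `full` (n x n) and, if requested,
#'   `loco` (named list of n x n matrices, one per chromosome).  With a
#'   single chromosome the LOCO exclusion would empty the marker set; a
#'   zero matrix is returned for that chromosome with a warning.
#' @export
calc_kinship <- function(probs, map = NULL, loco = TRUE) {
  map <- map %||% attr(probs, "map")
  if (is.null(map)) stopf("no marker map supplied or attached to `probs`")
  n <- dim(probs)[1]; M <- dim(probs)[2]
  if (nrow(map) != M) stopf("map rows (%d) != markers in probs (%d)", nrow(map), M)
  # unfold to n x (M*8); cross products per chromosome, then combine
  chroms <- unique(map$chrom)
  parts <- lapply(chroms, function(cc) {
    idx <- which(map$chrom == cc)
    Pm <- matrix(probs[, idx, , drop = FALSE], nrow = n)
    list(G = tcrossprod(Pm), m = length(idx))
  })
  names(parts) <- chroms
  Gtot <- Reduce(`+`, lapply(parts, `[[`, "G"))
  Mtot <- sum(vapply(parts, `[[`, integer(1), "m"))
  dn <- list(rownames(probs), rownames(probs))
  full <- Gtot / Mtot
  dimnames(full) <- dn
  out <- list(full = full, loco = NULL)
  if (loco) {
    if (length(chroms) < 2L) {
      warnf("single chromosome: LOCO exclusion would leave no markers; using a zero kinship")
      out$loco <- stats::setNames(
        list(matrix(0, n, n, dimnames = dn)), chroms)
    } else {
      out$loco <- lapply(chroms, function(cc) {
        K <- (Gtot - parts[[cc]]$G) / (Mtot - parts[[cc]]$m)
        dimnames(K) <- dn
        K
      })
      names(out$loco) <- chroms
    }
  }
  class(out) <- "kinship_set"
  out
}

#' @export
print.kinship_set <- function(x, ...) {
  cat(sprintf("Kinship set: %d individuals, %s\n", nrow(x$full),
              if (is.null(x$loco)) "full matrix only"
              else sprintf("full + %d LOCO matrices", length(x$loco))))
  cat(sprintf("  mean diagonal %.3f, mean off-diagonal %.3f\n",
              mean(diag(x$full)),
              (sum(x$full) - sum(diag(x$full))) / (nrow(x$full)^2 - nrow(x$full))))
  invisible(x)
}
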