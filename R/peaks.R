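# Turning LOD curves + thresholds into classified, characterized QTL.

#' Find per-chromosome LOD peaks above a threshold
#'
#' At most one peak per chromosome per phenotype: the maximum-LOD marker
#' on that chromosome if its LOD strictly exceeds the threshold (ties
#' broken by smallest position).  A phenotype exceeding the threshold on
#' several chromosomes yields several peaks ("multiple mappings").
#'
#' @param scan A `qtl_scan` object.
#' @param threshold Single LOD threshold, or a named vector with one
#'   threshold per phenotype.
#' @return Data frame: phenotype, chrom, marker, pos_mb, lod, threshold.
#' @export
find_peaks <- function(scan, threshold) {
  stopifnot(inherits(scan, "qtl_scan"))
  phenos <- colnames(scan$lod)
  thr <- if (length(threshold) == 1L && is.null(names(threshold)))
    stats::setNames(rep(threshold, length(phenos)), phenos)
  else threshold[phenos]
  if (any(is.na(thr))) stopf("missing threshold for some phenotypes")
  if (any(thr <= 0)) stopf("thresholds must be positive")
  out <- list()
  for (ph in phenos) {
    lodv <- scan$lod[, ph]
    for (cc in unique(scan$map$chrom)) {
      idx <- which(scan$map$chrom == cc)
      li <- lodv[idx]
      best <- idx[which.max(li)]  # which.max takes the first (smallest pos) tie
      if (lodv[best] > thr[ph]) {
        out[[length(out) + 1L]] <- data.frame(
          phenotype = ph, chrom = cc, marker = scan$map$marker[best],
          pos_mb = scan$map$pos_mb[best], lod = lodv[best],
          threshold = unname(thr[ph]), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(phenotype = character(), chrom = character(),
                      marker = character(), pos_mb = numeric(),
                      lod = numeric(), threshold = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' LOD-drop support interval around a peak
#'
#' Walking outward from the peak marker (inclusive), each bound is the
#' position of the first marker whose LOD is at or below `peak - drop`;
#' if no marker qualifies before the chromosome end, the bound is the
#' terminal marker position.  The default 1.8-LOD drop approximates 95%
#' coverage in an intercross-like design.
#'
#' @param lod LOD values along one chromosome (marker order).
#' @param pos_mb Marker positions (Mb), same length, increasing.
#' @param peak_index Index of the peak marker in `lod`.
#' @param drop LOD-drop defining the interval (default 1.8).
#' @return List: `lo`, `hi` (Mb), `drop`.
#' @export
support_interval <- function(lod, pos_mb, peak_index, drop = 1.8) {
  stopifnot(length(lod) == length(pos_mb), drop >= 0,
            peak_index >= 1, peak_index <= length(lod))
  cut <- lod[peak_index] - drop
  lo_idx <- peak_index
  repeat {
    if (lod[lo_idx] <= cut || lo_idx == 1L) break
    lo_idx <- lo_idx - 1L
  }
  hi_idx <- peak_index
  repeat {
    if (lod[hi_idx] <= cut || hi_idx == length(lod)) break
    hi_idx <- hi_idx + 1L
  }
  list(lo = pos_mb[lo_idx], hi = pos_mb[hi_idx], drop = drop)
}

#' Classify a QTL peak as cis or trans
#'
#' Cis iff the peak marker is on the feature's chromosome and within
#' `window_mb` (inclusive) of its transcription start site; otherwise
#' trans (a different chromosome is always trans).
#'
#' @param peak_chrom,peak_mb Peak marker chromosome and position.
#' @param tss_chrom,tss_mb Feature TSS chromosome and position.
#' @param window_mb Cis window (default 4, alternate 1).
#' @return `"cis"` or `"trans"`.
#' @export
classify_peak <- function(peak_chrom, peak_mb, tss_chrom, tss_mb,
                          window_mb = 4.0) {
  if (window_mb <= 0) stopf("cis window must be positive")
  if (is.na(tss_chrom) || is.na(tss_mb)) stopf("missing TSS annotation")
  if (as.character(peak_chrom) == as.character(tss_chrom) &&
      abs(peak_mb - tss_mb) <= window_mb) "cis" else "trans"
}

#' Phenotypic variance explained by a marker
#'
#' Difference in plain least-squares (Haley-Knott) R-squared between the
#' full model (covariates + 8 founder dosages) and the null model
#' (covariates only).  Deliberately unmixed - no kinship - even though the
#' scan itself is a mixed model.
#'
#' @param probs Allele-probability tensor.
#' @param marker Marker id.
#' @param pheno Phenotype vector.
#' @param addcovar Optional covariates.
#' @return R-squared difference in `[0, 1]`.
#' @export
variance_explained <- function(probs, marker, pheno, addcovar = NULL) {
  mi <- match(marker, dimnames(probs)[[2]])
  if (is.na(mi)) stopf("marker '%s' not found", marker)
  n <- length(pheno)
  X0 <- build_covar(addcovar, n)
  check_full_rank(X0)
  Z <- probs[, mi, ]
  tss <- sum((pheno - mean(pheno))^2)
  if (tss <= 0) return(0)
  r0 <- sum(stats::lm.fit(X0, pheno)$residuals^2)
  r1 <- sum(stats::lm.fit(cbind(X0, Z), pheno)$residuals^2)
  max((r0 - r1) / tss, 0)
}

#' Characterize significant QTL peaks
#'
#' Assembles the full QTL table: per-chromosome peaks above their
#' thresholds, 1.8-LOD support intervals, cis/trans calls against the
#' feature TSS, Haley-Knott variance explained, BLUP founder effects, and
#' narrow-sense heritability (full kinship).
#'
#' @param scan A `qtl_scan`.
#' @param pheno Phenotype matrix (individuals x phenotypes) the scan was
#'   run on.
#' @param probs Allele-probability tensor.
#' @param threshold Scalar or per-phenotype named thresholds.
#' @param annot Feature annotation data frame: `feature`, `class`
#'   ("mrna"/"mirna"), `chrom`, `tss_mb`.  Features without a TSS are
#'   excluded with a warning.
#' @param kinship Optional `kinship_set` (LOCO for BLUPs, full for h2).
#' @param addcovar Optional covariates (used for variance explained and
#'   BLUPs).
#' @param window_mb Cis window (default 4).
#' @param drop LOD drop for support intervals (default 1.8).
#' @param blup Compute BLUP founder effects (default TRUE)?
#' @param herit Compute narrow-sense heritability (default TRUE, needs
#'   `kinship`)?
#' @return Data frame of class `qtl_peaks`, one row per QTL: phenotype,
#'   class, model, chrom, peak_mb, marker, lod, threshold, ci_lo, ci_hi,
#'   cis_trans, var_explained, h2, eff_A..eff_H.
#' @export
characterize_qtl <- function(scan, pheno, probs, threshold, annot,
                             kinship = NULL, addcovar = NULL,
                             window_mb = 4.0, drop = 1.8,
                             blup = TRUE, herit = TRUE) {
  pheno <- as_pheno_matrix(pheno)
  peaks <- find_peaks(scan, threshold)
  if (nrow(peaks) > 0) {
    no_tss <- setdiff(peaks$phenotype, annot$feature[!is.na(annot$tss_mb)])
    if (length(no_tss) > 0) {
      warnf("excluding %d feature(s) without TSS annotation: %s",
            length(no_tss), paste(utils::head(no_tss, 5), collapse = ", "))
      peaks <- peaks[!peaks$phenotype %in% no_tss, , drop = FALSE]
    }
  }
  eff_cols <- paste0("eff_", names(do_founders))
  empty <- data.frame(phenotype = character(), class = character(),
                      model = character(), chrom = character(),
                      marker = character(), peak_mb = numeric(),
                      lod = numeric(), threshold = numeric(),
                      ci_lo = numeric(), ci_hi = numeric(),
                      cis_trans = character(), var_explained = numeric(),
                      h2 = numeric(), stringsAsFactors = FALSE)
  for (cc in eff_cols) empty[[cc]] <- numeric(0)
  if (nrow(peaks) == 0) return(structure(empty, class = c("qtl_peaks", "data.frame")))

  h2v <- NULL
  if (herit && !is.null(kinship)) {
    uph <- unique(peaks$phenotype)
    h2v <- est_herit(pheno[, uph, drop = FALSE], kinship, addcovar)
  }
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    pk <- peaks[i, ]
    idx <- which(scan$map$chrom == pk$chrom)
    ci <- support_interval(scan$lod[idx, pk$phenotype],
                           scan$map$pos_mb[idx],
                           match(pk$marker, scan$map$marker[idx]), drop)
    ai <- match(pk$phenotype, annot$feature)
    cls <- classify_peak(pk$chrom, pk$pos_mb, annot$chrom[ai],
                         annot$tss_mb[ai], window_mb)
    ve <- variance_explained(probs, pk$marker, pheno[, pk$phenotype], addcovar)
    row <- data.frame(pk[, c("phenotype", "chrom", "marker", "pos_mb",
                             "lod", "threshold")],
                      class = annot$class[ai], model = scan$model,
                      ci_lo = ci$lo, ci_hi = ci$hi, cis_trans = cls,
                      var_explained = ve,
                      h2 = if (is.null(h2v)) NA_real_ else unname(h2v[pk$phenotype]),
                      stringsAsFactors = FALSE)
    if (blup) {
      bl <- blup_effects(probs, pk$marker, pheno[, pk$phenotype],
                         kinship, addcovar, map = scan$map)
      row[eff_cols] <- as.list(bl$effects)
    } else {
      row[eff_cols] <- NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "pos_mb"] <- "peak_mb"
  out <- out[, c("phenotype", "class", "model", "chrom", "marker", "peak_mb",
                 "lod", "threshold", "ci_lo", "ci_hi", "cis_trans",
                 "var_explained", "h2", eff_cols)]
  rownames(out) <- NULL
  structure(out, class = c("qtl_peaks", "data.frame"))
}

#' @export
print.qtl_peaks <- function(x, ...) {
  cat(sprintf("QTL table: %d peak(s); %d cis, %d trans\n", nrow(x),
              sum(x$cis_trans == "cis"), sum(x$cis_trans == "trans")))
  print.data.frame(utils::head(as.data.frame(x)[, c("phenotype", "chrom",
    "peak_mb", "lod", "threshold", "cis_trans", "var_explained", "h2")], 10),
    digits = 3)
  if (nrow(x) > 10) cat(sprintf("  ... and %d more\n", nrow(x) - 10))
  invisible(x)
}
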