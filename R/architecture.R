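# Downstream architecture statistics: founder enrichment, colocalization,
# miRNA-mRNA correlation structure, Fisher tables, differential expression,
# and allele-by-diet divergence ranking.

#' Founder-allele enrichment across QTL peaks
#'
#' Mean-center-scales each peak's 8 founder BLUP effects, then tests
#' whether the absolute scaled effects differ among founders
#' (Kruskal-Wallis across the 8 founder groups) with Dunn's post hoc
#' pairwise comparisons (pooled-rank z statistics, BH-adjusted).
#'
#' @param effects Numeric matrix, peaks x 8 founders (columns in A-H
#'   order; `eff_A`..`eff_H` names accepted).
#' @return List of class `founder_enrichment`: `scaled` (centered/scaled
#'   effect matrix), `kruskal` (htest), `dunn` (data frame: founder1,
#'   founder2, z, p, p_adj).
#' @export
founder_enrichment <- function(effects) {
  effects <- as.matrix(effects)
  if (nrow(effects) < 2L) stopf("need at least 2 peaks")
  if (ncol(effects) != 8L) stopf("expected 8 founder effect columns")
  colnames(effects) <- names(do_founders)
  sds <- apply(effects, 1, stats::sd)
  if (any(sds == 0)) stopf("constant effect vector; cannot scale")
  scaled <- sweep(sweep(effects, 1, rowMeans(effects)), 1, sds, "/")
  vals <- abs(as.vector(scaled))
  grp <- factor(rep(colnames(scaled), each = nrow(scaled)),
                levels = names(do_founders))
  if (nlevels(droplevels(grp)) < 2L) stopf("fewer than 2 founder groups populated")
  kw <- stats::kruskal.test(vals, grp)
  dunn <- dunn_test(vals, grp)
  structure(list(scaled = scaled, kruskal = kw, dunn = dunn),
            class = "founder_enrichment")
}

# Dunn's post hoc test on pooled ranks with tie correction and BH
# adjustment across all pairwise comparisons.
dunn_test <- function(x, g) {
  g <- droplevels(as.factor(g))
  N <- length(x)
  rk <- rank(x)
  rbar <- tapply(rk, g, mean)
  ni <- tapply(rk, g, length)
  ties <- table(rk)
  tie_adj <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_adj
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(pr) {
    (rbar[pr[1]] - rbar[pr[2]]) /
      sqrt(s2 * (1 / ni[pr[1]] + 1 / ni[pr[2]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(founder1 = pairs[1, ], founder2 = pairs[2, ],
             z = as.numeric(z), p = as.numeric(p),
             p_adj = stats::p.adjust(p, "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.founder_enrichment <- function(x, ...) {
  cat(sprintf("Founder enrichment over %d peaks\n", nrow(x$scaled)))
  cat(sprintf("  Kruskal-Wallis chi2 = %.2f, p = %.3g\n",
              unname(x$kruskal$statistic), x$kruskal$p.value))
  sig <- x$dunn[x$dunn$p_adj < 0.05, ]
  cat(sprintf("  Dunn pairs with BH p < 0.05: %d of %d\n", nrow(sig), nrow(x$dunn)))
  invisible(x)
}

#' Colocalize eQTL and mirQTL by support-interval overlap
#'
#' All same-chromosome pairs whose closed support intervals overlap, with
#' the peak-to-peak distance in Mb (0 means the same marker).
#'
#' @param eqtl,mirqtl QTL tables (as from [characterize_qtl()]) with
#'   columns phenotype, chrom, peak_mb, ci_lo, ci_hi.
#' @return Data frame: mirqtl, eqtl, chrom, distance_mb, plus both
#'   intervals.
#' @export
colocalize <- function(eqtl, mirqtl) {
  need <- c("phenotype", "chrom", "peak_mb", "ci_lo", "ci_hi")
  stopifnot(all(need %in% names(eqtl)), all(need %in% names(mirqtl)))
  out <- list()
  for (i in seq_len(nrow(mirqtl))) for (j in seq_len(nrow(eqtl))) {
    if (mirqtl$chrom[i] != eqtl$chrom[j]) next
    if (mirqtl$ci_lo[i] <= eqtl$ci_hi[j] && eqtl$ci_lo[j] <= mirqtl$ci_hi[i]) {
      out[[length(out) + 1L]] <- data.frame(
        mirqtl = mirqtl$phenotype[i], eqtl = eqtl$phenotype[j],
        chrom = mirqtl$chrom[i],
        distance_mb = abs(mirqtl$peak_mb[i] - eqtl$peak_mb[j]),
        mirqtl_lo = mirqtl$ci_lo[i], mirqtl_hi = mirqtl$ci_hi[i],
        eqtl_lo = eqtl$ci_lo[j], eqtl_hi = eqtl$ci_hi[j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(mirqtl = character(), eqtl = character(),
                      chrom = character(), distance_mb = numeric(),
                      mirqtl_lo = numeric(), mirqtl_hi = numeric(),
                      eqtl_lo = numeric(), eqtl_hi = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Reports the sample odds ratio `(a*d)/(b*c)` (not the conditional MLE)
#' together with the exact two-sided hypergeometric p-value and the
#' conditional confidence interval.
#'
#' @param tab 2x2 matrix of nonnegative integer counts, rows = first
#'   factor, columns = second factor.
#' @return Object of class `fisher_result`: `odds_ratio`, `p_value`,
#'   `conf_int`, `table`.  A zero denominator yields an infinite odds
#'   ratio (flagged) with the p-value still computed.
#' @export
fisher_association <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stopf("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stopf("cells must be nonnegative integers")
  orat <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  ft <- stats::fisher.test(tab)
  structure(list(odds_ratio = orat, p_value = ft$p.value,
                 conf_int = unname(ft$conf.int), table = tab,
                 infinite_or = !is.finite(orat)),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("Fisher's exact test: sample OR = %.3g (95%% CI %.3g-%.3g), p = %.4g\n",
              x$odds_ratio, x$conf_int[1], x$conf_int[2], x$p_value))
  invisible(x)
}

#' miRNA-mRNA correlation structure
#'
#' Computes every pairwise Spearman correlation between the miRNA and
#' mRNA panels (t-approximation p-values), adjusts across the full
#' cross-product by Benjamini-Hochberg, annotates each pair with the
#' mRNA's eQTL category and known-interaction status, and summarizes:
#' pairwise Wilcoxon rank-sum tests on |rho| between the three eQTL
#' categories (among BH-significant pairs) and Fisher's exact test of
#' mapping status against known interaction.
#'
#' @param mirna,mrna Expression matrices, features x individuals, sharing
#'   individual ids (columns); at least 3 shared individuals.
#' @param eqtl_category Named character vector over mRNA features with
#'   values "cis", "trans" or "no-eQTL"; mRNAs with multiple mappings
#'   should be listed in `multi_mapping` and are removed.
#' @param catalog Optional known-interaction catalog: data frame with
#'   columns `mirna`, `target`.
#' @param multi_mapping Character vector of mRNA features to drop
#'   (multiple mappings).
#' @param alpha BH significance level (default 0.05).
#' @return List of class `cor_structure`: `records` (one row per pair:
#'   mirna, mrna, rho, p, p_adj, significant, category,
#'   known_interaction), `category_medians`, `wilcox` (pairwise tests),
#'   `fisher` (mapping x interaction among significant pairs), `n_pairs`,
#'   `n_significant`.
#' @export
correlation_structure <- function(mirna, mrna, eqtl_category,
                                  catalog = NULL, multi_mapping = character(),
                                  alpha = 0.05) {
  shared <- intersect(colnames(mirna), colnames(mrna))
  if (length(shared) < 3L) stopf("fewer than 3 shared individuals")
  mrna <- mrna[!rownames(mrna) %in% multi_mapping, shared, drop = FALSE]
  mirna <- mirna[, shared, drop = FALSE]
  n <- length(shared)
  rho <- stats::cor(t(mirna), t(mrna), method = "spearman")
  r <- pmin(pmax(as.vector(rho), -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  p_adj <- stats::p.adjust(p, "BH")
  records <- data.frame(
    mirna = rep(rownames(mirna), times = ncol(rho)),
    mrna = rep(colnames(rho), each = nrow(rho)),
    rho = r, p = p, p_adj = p_adj, significant = p_adj < alpha,
    stringsAsFactors = FALSE)
  records$category <- unname(eqtl_category[records$mrna])
  records$category[is.na(records$category)] <- "no-eQTL"
  records$known_interaction <- FALSE
  if (!is.null(catalog) && nrow(catalog) > 0) {
    key <- paste(records$mirna, records$mrna)
    records$known_interaction <- key %in% paste(catalog$mirna, catalog$target)
  }
  sig <- records[records$significant, , drop = FALSE]
  med <- tapply(abs(sig$rho), sig$category, stats::median)
  cats <- intersect(c("cis", "trans", "no-eQTL"), unique(sig$category))
  wx <- NULL
  if (length(cats) >= 2) {
    prs <- utils::combn(cats, 2)
    wx <- data.frame(cat1 = prs[1, ], cat2 = prs[2, ],
                     p = apply(prs, 2, function(pr) {
                       stats::wilcox.test(abs(sig$rho[sig$category == pr[1]]),
                                          abs(sig$rho[sig$category == pr[2]]))$p.value
                     }), stringsAsFactors = FALSE)
  }
  fis <- NULL
  if (any(sig$known_interaction)) {
    mapping <- sig$category %in% c("cis", "trans")
    tb <- table(factor(mapping, c(TRUE, FALSE)),
                factor(sig$known_interaction, c(TRUE, FALSE)))
    fis <- fisher_association(matrix(as.integer(tb), 2, 2))
  }
  structure(list(records = records, category_medians = med, wilcox = wx,
                 fisher = fis, n_pairs = nrow(records),
                 n_significant = sum(records$significant), alpha = alpha),
            class = "cor_structure")
}

#' @export
print.cor_structure <- function(x, ...) {
  cat(sprintf("miRNA-mRNA correlation structure: %d pairs, %d BH-significant (alpha = %g)\n",
              x$n_pairs, x$n_significant, x$alpha))
  if (length(x$category_medians))
    cat("  median |rho| by category:",
        paste(sprintf("%s = %.3f", names(x$category_medians),
                      x$category_medians), collapse = ", "), "\n")
  invisible(x)
}

#' Expression filter configuration
#'
#' Defaults follow the standard panel filters: mRNA kept when the
#' log-intensity is >= 4 in at least 25% of samples; miRNA kept when the
#' abundance is >= 50 RPMMM in at least ~25% of samples.
#'
#' @param mrna_floor,mrna_prevalence mRNA expression floor and minimum
#'   fraction of samples at/above it.
#' @param mirna_floor,mirna_prevalence Same for miRNA.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(mrna_floor = 4, mrna_prevalence = 0.25,
                          mirna_floor = 50, mirna_prevalence = 0.25) {
  check_prob(mrna_prevalence, "mrna_prevalence", lo_open = TRUE)
  check_prob(mirna_prevalence, "mirna_prevalence", lo_open = TRUE)
  structure(list(mrna_floor = mrna_floor, mrna_prevalence = mrna_prevalence,
                 mirna_floor = mirna_floor, mirna_prevalence = mirna_prevalence),
            class = "filter_config")
}

#' Expression filter: floor value in a minimum fraction of samples
#'
#' A feature passes when its value is at or above `floor` in at least
#' `prevalence` of the samples (both inclusive, so a feature exactly at
#' the floor in exactly the required fraction passes).
#'
#' @param panel Features x individuals matrix.
#' @param floor Expression floor.
#' @param prevalence Minimum fraction of samples in `(0, 1]`.
#' @return Logical vector over features.
#' @export
expression_filter <- function(panel, floor, prevalence) {
  rowMeans(panel >= floor) >= prevalence
}

#' Differential expression by diet (Wilcoxon rank-sum + BH)
#'
#' Features failing the expression filter are excluded before testing.
#' The Wilcoxon rank-sum test compares the two diet groups per feature;
#' p-values are BH-adjusted and significance is called at BH p < alpha.
#'
#' @param panel Features x individuals matrix (native scale for the
#'   filter).
#' @param diet Factor of length individuals with exactly two levels, each
#'   with >= 2 individuals.
#' @param floor,prevalence Expression filter parameters (see
#'   [expression_filter()]).
#' @param alpha Significance level on BH-adjusted p (default 0.05).
#' @return Data frame: feature, p, p_adj, significant, direction (sign of
#'   the second-level minus first-level median), plus the filter flag for
#'   all input features.
#' @export
differential_expression <- function(panel, diet, floor = 4,
                                    prevalence = 0.25, alpha = 0.05) {
  diet <- as.factor(diet)
  if (nlevels(diet) != 2L || any(table(diet) < 2L))
    stopf("need two diet groups with at least 2 individuals each")
  keep <- expression_filter(panel, floor, prevalence)
  g1 <- diet == levels(diet)[1]
  res <- data.frame(feature = rownames(panel), filtered_in = keep,
                    p = NA_real_, p_adj = NA_real_,
                    significant = FALSE, direction = NA_real_,
                    stringsAsFactors = FALSE)
  tested <- which(keep)
  pv <- vapply(tested, function(i) {
    suppressWarnings(stats::wilcox.test(panel[i, g1], panel[i, !g1])$p.value)
  }, numeric(1))
  res$p[tested] <- pv
  res$p_adj[tested] <- stats::p.adjust(pv, "BH")
  res$significant[tested] <- res$p_adj[tested] < alpha
  res$direction[tested] <- sign(apply(panel[tested, !g1, drop = FALSE], 1,
                                      stats::median) -
                                apply(panel[tested, g1, drop = FALSE], 1,
                                      stats::median))
  res
}

#' Rank allele-by-diet interactions at interactive-model eQTL
#'
#' For each interactive-model eQTL: (1) a plain least-squares ANOVA
#' F-test of the allele-by-diet block (covariates + dosages +
#' dosage-by-diet vs covariates + dosages), BH-adjusted; (2) BH-significant
#' phenotypes are kept only if they have an eQTL in BOTH diet-subset
#' models that is concordant (same chromosome, overlapping support
#' intervals, same cis/trans class); (3) per founder, the percent
#' difference of the HFCA BLUP effect relative to the HP effect (HP as
#' reference, with a floor `eps = eps_frac * SD` of that phenotype's
#' founder effects guarding near-zero references); (4) the divergence
#' score is the sum of absolute percent differences over the 8 founders,
#' ranked descending.
#'
#' @param int_peaks Interactive-model QTL table ([characterize_qtl()]).
#' @param hfca_peaks,hp_peaks Diet-subset QTL tables carrying BLUP founder
#'   effect columns `eff_A`..`eff_H`.
#' @param pheno Phenotype matrix (individuals x phenotypes) of the full
#'   cohort.
#' @param probs Allele-probability tensor (full cohort).
#' @param diet Factor over individuals (reference level first).
#' @param eps_frac Floor fraction for the percent-difference reference.
#' @param alpha BH significance level for the interaction ANOVA.
#' @return Data frame sorted by descending divergence score: phenotype,
#'   marker, p_interaction, p_adj, significant, concordant, pd_A..pd_H,
#'   divergence_score.
#' @export
allele_diet_ranking <- function(int_peaks, hfca_peaks, hp_peaks, pheno,
                                probs, diet, eps_frac = 0.05, alpha = 0.05) {
  pheno <- as_pheno_matrix(pheno)
  diet <- as.factor(diet)
  dind <- as.numeric(diet == levels(diet)[2])
  eff_cols <- paste0("eff_", names(do_founders))
  pd_cols <- paste0("pd_", names(do_founders))
  if (nrow(int_peaks) == 0) {
    out <- data.frame(phenotype = character(), marker = character(),
                      p_interaction = numeric(), p_adj = numeric(),
                      significant = logical(), concordant = logical(),
                      stringsAsFactors = FALSE)
    for (cc in c(pd_cols, "divergence_score")) out[[cc]] <- numeric(0)
    return(out)
  }
  pint <- vapply(seq_len(nrow(int_peaks)), function(i) {
    y <- pheno[, int_peaks$phenotype[i]]
    Z <- probs[, int_peaks$marker[i], ]
    interaction_anova_p(y, Z, dind)
  }, numeric(1))
  out <- data.frame(phenotype = int_peaks$phenotype,
                    marker = int_peaks$marker,
                    p_interaction = pint,
                    p_adj = stats::p.adjust(pint, "BH"),
                    stringsAsFactors = FALSE)
  out$significant <- out$p_adj < alpha
  conc <- vapply(out$phenotype, function(ph)
    diet_concordant(ph, hfca_peaks, hp_peaks), logical(1))
  out$concordant <- unname(conc)
  out[c(pd_cols, "divergence_score")] <- NA_real_
  for (i in which(out$significant & out$concordant)) {
    ph <- out$phenotype[i]
    bh <- as.numeric(hfca_peaks[match(ph, hfca_peaks$phenotype), eff_cols])
    bp <- as.numeric(hp_peaks[match(ph, hp_peaks$phenotype), eff_cols])
    dv <- divergence_score(bh, bp, eps_frac)
    out[i, pd_cols] <- dv$percent_diff
    out$divergence_score[i] <- dv$score
  }
  out[order(-ifelse(is.na(out$divergence_score), -Inf, out$divergence_score),
            out$p_adj), , drop = FALSE]
}

#' Founder-effect divergence between two diet models
#'
#' Per-founder percent difference of one diet model's BLUP effects
#' relative to the reference diet's effects, with a floor of
#' `eps_frac * SD` of all 16 effect values guarding near-zero references,
#' and the summed absolute percent difference as the divergence score.
#' The score is invariant to a common positive rescaling of both effect
#' vectors.
#'
#' @param eff Focal-model founder effects (length 8).
#' @param eff_ref Reference-model founder effects (length 8).
#' @param eps_frac Floor fraction (default 0.05).
#' @return List: `percent_diff` (length 8), `score` (sum of absolute
#'   percent differences).
#' @export
divergence_score <- function(eff, eff_ref, eps_frac = 0.05) {
  stopifnot(length(eff) == 8L, length(eff_ref) == 8L)
  eps <- eps_frac * stats::sd(c(eff, eff_ref))
  if (!is.finite(eps) || eps <= 0) eps <- .Machine$double.eps
  pd <- 100 * (eff - eff_ref) / pmax(abs(eff_ref), eps)
  list(percent_diff = pd, score = sum(abs(pd)))
}

# F-test of the dosage-by-diet block: [1, d, Z] vs [1, d, Z, Z*d], plain
# least squares, rank-aware.
interaction_anova_p <- function(y, Z, dind) {
  n <- length(y)
  Xr <- cbind(1, dind, Z)
  Xf <- cbind(Xr, Z * dind)
  qr_r <- qr(Xr); qr_f <- qr(Xf)
  rss_r <- sum(qr.resid(qr_r, y)^2)
  rss_f <- sum(qr.resid(qr_f, y)^2)
  df1 <- qr_f$rank - qr_r$rank
  df2 <- n - qr_f$rank
  if (df1 <= 0 || df2 <= 0) return(NA_real_)
  fstat <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  stats::pf(fstat, df1, df2, lower.tail = FALSE)
}

# A phenotype is diet-concordant when it has a peak in both diet-subset
# tables on the same chromosome, with overlapping support intervals and
# matching cis/trans class.
diet_concordant <- function(ph, hfca_peaks, hp_peaks) {
  ah <- hfca_peaks[hfca_peaks$phenotype == ph, , drop = FALSE]
  ap <- hp_peaks[hp_peaks$phenotype == ph, , drop = FALSE]
  if (nrow(ah) == 0 || nrow(ap) == 0) return(FALSE)
  for (i in seq_len(nrow(ah))) for (j in seq_len(nrow(ap))) {
    if (ah$chrom[i] == ap$chrom[j] &&
        ah$ci_lo[i] <= ap$ci_hi[j] && ap$ci_lo[j] <= ah$ci_hi[i] &&
        ah$cis_trans[i] == ap$cis_trans[j]) return(TRUE)
  }
  FALSE
}
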