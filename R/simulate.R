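# Synthetic DO-style data generator: founder mosaics, allele probabilities,
# and expression panels with planted QTL ground truth.

#' Configuration for the synthetic DO-style generator
#'
#' Defaults emulate the study cohort the package is designed around: 243
#' individuals in an unbalanced 134:109 two-diet split, eight founder
#' haplotypes at near-equal frequency, and a miRNA panel of 246 features.
#' The mRNA panel defaults to a desk-scale few hundred features; the
#' genome to two 100-Mb chromosomes.
#'
#' @param n_individuals Number of individuals (>= 8).
#' @param chromosomes Data frame with columns `chrom` (character),
#'   `length_mb` (positive), `n_markers` (>= 2): one row per chromosome.
#' @param recomb_rate Expected founder-switch events per Mb per homolog
#'   (> 0; a homolog on a 100-Mb chromosome at 0.05/Mb carries 5 expected
#'   switches).
#' @param n_mrna,n_mirna Number of mRNA / miRNA features.
#' @param diet_labels Two diet labels; the first is the reference level.
#' @param hfca_fraction Fraction of individuals assigned the second
#'   (non-reference) diet; default mirrors the 134:109 split.
#' @param softening Probability mass spread uniformly over founders when
#'   converting true mosaics to allele probabilities (in `[0, 0.5)`),
#'   emulating probabilistic genotype reconstruction.
#' @param seed Master integer seed; all generator sub-streams are derived
#'   from it by stable hashing so that, e.g., adding phenotypes does not
#'   perturb genotypes.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 243L,
                       chromosomes = data.frame(
                         chrom = c("1", "2"),
                         length_mb = c(100, 100),
                         n_markers = c(50L, 50L),
                         stringsAsFactors = FALSE
                       ),
                       recomb_rate = 0.05,
                       n_mrna = 300L,
                       n_mirna = 246L,
                       diet_labels = c("HP", "HFCA"),
                       hfca_fraction = 134 / 243,
                       softening = 0.02,
                       seed = 1L) {
  n_individuals <- check_count(n_individuals, "n_individuals", min = 8L)
  if (!is.data.frame(chromosomes) ||
      !all(c("chrom", "length_mb", "n_markers") %in% names(chromosomes)) ||
      nrow(chromosomes) < 1L)
    stopf("`chromosomes` must be a data frame with columns chrom, length_mb, n_markers")
  if (any(chromosomes$length_mb <= 0))
    stopf("chromosome lengths must be positive")
  if (any(chromosomes$n_markers < 2L))
    stopf("every chromosome needs at least 2 markers")
  if (!is.numeric(recomb_rate) || recomb_rate < 0)
    stopf("`recomb_rate` must be >= 0")
  if (length(diet_labels) != 2L) stopf("`diet_labels` must have two levels")
  check_prob(hfca_fraction, "hfca_fraction", lo_open = TRUE, hi_open = TRUE)
  check_prob(softening, "softening", lo = 0, hi = 0.5, hi_open = TRUE)
  structure(list(
    n_individuals = n_individuals,
    chromosomes = chromosomes,
    recomb_rate = as.numeric(recomb_rate),
    n_mrna = check_count(n_mrna, "n_mrna", min = 0L),
    n_mirna = check_count(n_mirna, "n_mirna", min = 0L),
    diet_labels = as.character(diet_labels),
    hfca_fraction = as.numeric(hfca_fraction),
    softening = as.numeric(softening),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic DO simulation config\n")
  cat(sprintf("  individuals: %d (diets %s:%s = %d:%d)\n", x$n_individuals,
              x$diet_labels[2], x$diet_labels[1],
              round(x$hfca_fraction * x$n_individuals),
              x$n_individuals - round(x$hfca_fraction * x$n_individuals)))
  cat(sprintf("  chromosomes: %s\n",
              paste(sprintf("%s (%g Mb, %d markers)", x$chromosomes$chrom,
                            x$chromosomes$length_mb, x$chromosomes$n_markers),
                    collapse = ", ")))
  cat(sprintf("  recomb rate: %g switches/Mb; softening %g\n",
              x$recomb_rate, x$softening))
  cat(sprintf("  features: %d mRNA, %d miRNA; seed %d\n",
              x$n_mrna, x$n_mirna, x$seed))
  invisible(x)
}

# Evenly spaced marker map for a config.
marker_map_from_config <- function(config) {
  maps <- lapply(seq_len(nrow(config$chromosomes)), function(i) {
    cc <- config$chromosomes[i, ]
    pos <- seq(0.5, cc$length_mb - 0.5, length.out = cc$n_markers)
    data.frame(
      marker = sprintf("c%s_m%03d", cc$chrom, seq_len(cc$n_markers)),
      chrom = as.character(cc$chrom),
      pos_mb = pos,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, maps)
}

#' Simulate founder haplotype mosaics
#'
#' Each individual carries two homologs per chromosome.  Along a homolog,
#' founder-switch events occur as a Poisson process with rate
#' `recomb_rate` per Mb (a Markov switch process with no interference); at
#' each event the new founder is drawn uniformly from the seven other
#' founders, so every event is an observable switch and the expected event
#' count per homolog equals `recomb_rate * length_mb`.  The founder at the
#' chromosome start is uniform over all eight.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `founder_mosaics`: integer founder indices
#'   (1-8) for each homolog at each marker (`h1`, `h2`, individuals x
#'   markers), the marker `map`, and the per-homolog switch-event counts
#'   (`n_events`, individuals x 2).
#' @export
simulate_mosaics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  map <- marker_map_from_config(config)
  n <- config$n_individuals
  M <- nrow(map)
  ids <- sprintf("ind%03d", seq_len(n))
  h <- list(
    matrix(0L, n, M, dimnames = list(ids, map$marker)),
    matrix(0L, n, M, dimnames = list(ids, map$marker))
  )
  n_events <- matrix(0L, n, 2, dimnames = list(ids, c("h1", "h2")))
  with_seed(hash_seed(config$seed, "mosaics"), {
    for (ci in seq_len(nrow(config$chromosomes))) {
      cc <- config$chromosomes[ci, ]
      idx <- which(map$chrom == as.character(cc$chrom))
      pos <- map$pos_mb[idx]
      for (hom in 1:2) {
        for (i in seq_len(n)) {
          k <- stats::rpois(1L, config$recomb_rate * cc$length_mb)
          breaks <- sort(stats::runif(k, 0, cc$length_mb))
          founders <- integer(k + 1L)
          founders[1L] <- sample.int(8L, 1L)
          if (k > 0L) for (j in seq_len(k)) {
            founders[j + 1L] <- sample(setdiff(1:8, founders[j]), 1L)
          }
          seg <- findInterval(pos, breaks) + 1L
          h[[hom]][i, idx] <- founders[seg]
          n_events[i, hom] <- n_events[i, hom] + k
        }
      }
    }
  })
  structure(list(h1 = h[[1]], h2 = h[[2]], map = map, n_events = n_events,
                 config = config),
            class = "founder_mosaics")
}

#' @export
print.founder_mosaics <- function(x, ...) {
  cat(sprintf("Founder mosaics: %d individuals x %d markers x 2 homologs\n",
              nrow(x$h1), ncol(x$h1)))
  cat(sprintf("  mean switch events per homolog: %.2f\n", mean(x$n_events)))
  invisible(x)
}

#' Convert founder mosaics to an allele-probability tensor
#'
#' Entry `(i, m, f)` is the average over the two homologs of the indicator
#' that homolog carries founder `f`, with `1 - softening` of the mass on
#' the true assignment and `softening` spread uniformly over all eight
#' founders.  Every `(i, m)` slice sums to exactly 1.
#'
#' @param mosaics A [simulate_mosaics()] result.
#' @param softening Probability mass in `[0, 0.5)`; defaults to the
#'   config's value.
#' @return A numeric array (individuals x markers x 8) with founder letter
#'   dimnames; the marker map is attached as attribute `"map"`.
#' @export
mosaics_to_alleleprobs <- function(mosaics, softening = NULL) {
  stopifnot(inherits(mosaics, "founder_mosaics"))
  softening <- softening %||% mosaics$config$softening
  check_prob(softening, "softening", lo = 0, hi = 0.5, hi_open = TRUE)
  n <- nrow(mosaics$h1); M <- ncol(mosaics$h1)
  probs <- array(0, dim = c(n, M, 8),
                 dimnames = list(rownames(mosaics$h1), colnames(mosaics$h1),
                                 names(do_founders)))
  for (f in 1:8) {
    probs[, , f] <- ((mosaics$h1 == f) + (mosaics$h2 == f)) / 2
  }
  probs <- probs * (1 - softening) + softening / 8
  attr(probs, "map") <- mosaics$map
  probs
}

#' Assemble a planted ground truth for the expression simulator
#'
#' @param qtl Data frame of planted QTL with columns `phenotype`, `marker`,
#'   `class` ("cis"/"trans"), effect columns `eff_A`..`eff_H` and optional
#'   interaction columns `int_A`..`int_H` (trait units per founder dosage,
#'   applied to the non-reference diet).  Effect vectors are mean-centered
#'   on construction.  May be empty.
#' @param phenotypes Data frame with columns `phenotype`, `class`
#'   ("mrna"/"mirna"), `chrom`, `tss_mb`, `h2` (target narrow-sense
#'   heritability in `[0,1]`), `diet_effect` (additive shift of the
#'   non-reference diet, trait units).
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(qtl, phenotypes) {
  eff_cols <- paste0("eff_", names(do_founders))
  int_cols <- paste0("int_", names(do_founders))
  if (nrow(qtl) > 0) {
    stopifnot(all(c("phenotype", "marker", "class", eff_cols) %in% names(qtl)))
    if (!all(int_cols %in% names(qtl))) qtl[int_cols] <- 0
    # mean-center effect vectors so they are identified against an intercept
    qtl[eff_cols] <- sweep(as.matrix(qtl[eff_cols]), 1,
                           rowMeans(as.matrix(qtl[eff_cols])))
    qtl[int_cols] <- sweep(as.matrix(qtl[int_cols]), 1,
                           rowMeans(as.matrix(qtl[int_cols])))
  } else {
    qtl <- data.frame(phenotype = character(), marker = character(),
                      class = character(), stringsAsFactors = FALSE)
    for (cc in c(eff_cols, int_cols)) qtl[[cc]] <- numeric(0)
  }
  stopifnot(all(c("phenotype", "class", "chrom", "tss_mb", "h2",
                  "diet_effect") %in% names(phenotypes)))
  if (any(phenotypes$h2 < 0 | phenotypes$h2 > 1))
    stopf("target h2 must lie in [0, 1]")
  if (!all(qtl$phenotype %in% phenotypes$phenotype))
    stopf("planted QTL refer to unknown phenotypes")
  structure(list(qtl = qtl, phenotypes = phenotypes), class = "ground_truth")
}

#' Simulate an expression panel over given allele probabilities
#'
#' Each phenotype is built as planted-QTL dosage effects + diet main effect
#' + dosage-by-diet interaction effects (non-reference diet only) + a
#' polygenic draw with covariance proportional to the overall kinship +
#' i.i.d. noise.  The polygenic and noise variances are scaled so the
#' kinship-captured fraction of the background variance equals the target
#' narrow-sense heritability in expectation (kinship normalized to unit
#' mean diagonal); planted QTL effects ride on top of a unit-variance
#' background, so effect sizes are in background-SD units.
#'
#' Values are returned on the analysis (log-intensity-like) scale for all
#' features; see [simulate_do_dataset()] for the native miRNA RPMMM-like
#' scale.
#'
#' @param probs Allele-probability tensor (individuals x markers x 8).
#' @param truth A [ground_truth()] object.
#' @param covar Data frame with columns `id`, `diet` (factor, reference
#'   level first) aligned with `probs` rows.
#' @param seed Integer seed for the noise/polygenic stream.
#' @param kinship Optional full kinship matrix; computed from `probs` if
#'   missing.
#' @return Numeric matrix, features x individuals.
#' @export
simulate_expression <- function(probs, truth, covar, seed, kinship = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  n <- dim(probs)[1]
  if (nrow(covar) != n)
    stopf("dimension mismatch: probs has %d individuals, covariates %d",
          n, nrow(covar))
  if (!all(truth$qtl$marker %in% dimnames(probs)[[2]]))
    stopf("planted QTL markers missing from the allele-probability tensor")
  if (is.null(kinship)) {
    map <- attr(probs, "map")
    kinship <- calc_kinship(probs, map, loco = FALSE)$full
  }
  # normalize so a unit polygenic variance component yields unit trait variance
  Ks <- kinship * (n / sum(diag(kinship)))
  eg <- eigen(Ks, symmetric = TRUE)
  evals <- pmax(eg$values, 0)
  Lk <- eg$vectors %*% diag(sqrt(evals), n)

  diet_ind <- as.numeric(covar$diet == levels(covar$diet)[2])
  ph <- truth$phenotypes
  eff_cols <- paste0("eff_", names(do_founders))
  int_cols <- paste0("int_", names(do_founders))
  out <- matrix(0, nrow(ph), n, dimnames = list(ph$phenotype, rownames(probs)))
  with_seed(seed, {
    for (i in seq_len(nrow(ph))) {
      h2 <- ph$h2[i]
      bg <- if ("background_sd" %in% names(ph)) ph$background_sd[i] else 1
      g <- as.vector(Lk %*% stats::rnorm(n)) * sqrt(h2)
      e <- stats::rnorm(n, sd = sqrt(1 - h2))
      y <- bg * (g + e) + ph$diet_effect[i] * diet_ind
      pq <- truth$qtl[truth$qtl$phenotype == ph$phenotype[i], , drop = FALSE]
      if (nrow(pq) > 0) for (j in seq_len(nrow(pq))) {
        D <- probs[, pq$marker[j], ]
        y <- y + as.vector(D %*% as.numeric(pq[j, eff_cols])) +
          diet_ind * as.vector(D %*% as.numeric(pq[j, int_cols]))
      }
      out[i, ] <- y
    }
  })
  out
}

#' Simulate a complete DO-style dataset with planted QTL
#'
#' Convenience wrapper tying the generator together: founder mosaics,
#' allele probabilities, diet assignment, feature annotations (uniform
#' TSS), planted cis QTL (at the marker nearest the feature's TSS) and
#' trans QTL (at a random marker away from the TSS), and the simulated
#' expression panels.  mRNA values are emitted on a log-intensity-like
#' scale (analysis scale + 7); miRNA values on a nonnegative RPMMM-like
#' scale (`200 * 2^y`).
#'
#' @param config A [sim_config()] object.
#' @param n_cis_qtl,n_trans_qtl Number of mRNA features receiving a
#'   planted cis / trans QTL.
#' @param n_mirna_qtl Number of miRNA features receiving a planted cis QTL.
#' @param effect_size SD of the founder effect vector entries
#'   (background-SD units per dosage).
#' @param h2 Target narrow-sense heritability of every feature's
#'   polygenic background.
#' @param diet_effect_sd SD of per-feature diet main effects (0 disables).
#' @param cis_window_mb Planted cis QTL must lie within this window of the
#'   feature TSS.
#' @param truth Optional pre-built [ground_truth()] overriding the planted
#'   defaults (annotations are then taken from it).
#' @return Object of class `do_dataset`: `probs`, `map`, `expr` (features x
#'   individuals, analysis scale), `expr_native`, `annot`, `covar`,
#'   `truth`, `mosaics`, `config`.
#' @export
simulate_do_dataset <- function(config,
                                n_cis_qtl = 0L, n_trans_qtl = 0L,
                                n_mirna_qtl = 0L,
                                effect_size = 0.75, h2 = 0.3,
                                diet_effect_sd = 0.5,
                                cis_window_mb = 4.0,
                                truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  mosaics <- simulate_mosaics(config)
  probs <- mosaics_to_alleleprobs(mosaics)
  map <- mosaics$map
  n <- config$n_individuals

  covar <- with_seed(hash_seed(config$seed, "diet"), {
    n_hfca <- round(config$hfca_fraction * n)
    diet <- factor(sample(rep(config$diet_labels, c(n - n_hfca, n_hfca))),
                   levels = config$diet_labels)
    data.frame(id = rownames(probs), diet = diet, stringsAsFactors = FALSE)
  })

  if (is.null(truth)) {
    truth <- with_seed(hash_seed(config$seed, "effects"), {
      feats <- c(if (config$n_mrna > 0) sprintf("mrna_%04d", seq_len(config$n_mrna)),
                 if (config$n_mirna > 0) sprintf("mirna_%03d", seq_len(config$n_mirna)))
      cls <- c(rep("mrna", config$n_mrna), rep("mirna", config$n_mirna))
      chrom <- sample(as.character(config$chromosomes$chrom), length(feats),
                      replace = TRUE)
      len <- config$chromosomes$length_mb[match(chrom, as.character(config$chromosomes$chrom))]
      tss <- stats::runif(length(feats), 0, len)
      ph <- data.frame(phenotype = feats, class = cls, chrom = chrom,
                       tss_mb = tss, h2 = h2,
                       diet_effect = if (diet_effect_sd > 0)
                         stats::rnorm(length(feats), 0, diet_effect_sd) else 0,
                       stringsAsFactors = FALSE)
      qtl <- make_planted_qtl(ph, map, n_cis_qtl, n_trans_qtl, n_mirna_qtl,
                              effect_size, cis_window_mb)
      ground_truth(qtl, ph)
    })
  }

  expr <- simulate_expression(probs, truth, covar,
                              seed = hash_seed(config$seed, "noise"))
  annot <- truth$phenotypes[, c("phenotype", "class", "chrom", "tss_mb")]
  names(annot)[1] <- "feature"
  native <- expr
  is_mirna <- annot$class == "mirna"
  native[!is_mirna, ] <- expr[!is_mirna, , drop = FALSE] + 7
  native[is_mirna, ] <- 200 * 2^expr[is_mirna, , drop = FALSE]

  structure(list(probs = probs, map = map, expr = expr, expr_native = native,
                 annot = annot, covar = covar, truth = truth,
                 mosaics = mosaics, config = config),
            class = "do_dataset")
}

# Draw planted QTL rows for randomly chosen features.  Cis QTL sit at the
# marker nearest the feature's TSS (within the window); trans QTL at a
# random marker at least `cis_window_mb` from the TSS or on another
# chromosome.
make_planted_qtl <- function(ph, map, n_cis, n_trans, n_mirna_qtl,
                             effect_size, cis_window_mb) {
  eff_cols <- paste0("eff_", names(do_founders))
  mrna_pool <- ph$phenotype[ph$class == "mrna"]
  mirna_pool <- ph$phenotype[ph$class == "mirna"]
  cis_feats <- if (n_cis > 0) sample(mrna_pool, n_cis) else character()
  trans_feats <- if (n_trans > 0)
    sample(setdiff(mrna_pool, cis_feats), n_trans) else character()
  if (n_mirna_qtl > 0) cis_feats <- c(cis_feats, sample(mirna_pool, n_mirna_qtl))
  add_row <- function(feat, cls) {
    pinfo <- ph[ph$phenotype == feat, ]
    if (cls == "cis") {
      cand <- which(map$chrom == pinfo$chrom &
                      abs(map$pos_mb - pinfo$tss_mb) <= cis_window_mb)
      if (length(cand) == 0)  # nearest same-chromosome marker as fallback
        cand <- which(map$chrom == pinfo$chrom)
      mk <- cand[which.min(abs(map$pos_mb[cand] - pinfo$tss_mb))]
    } else {
      cand <- which(map$chrom != pinfo$chrom |
                      abs(map$pos_mb - pinfo$tss_mb) > cis_window_mb)
      mk <- sample(cand, 1L)
    }
    eff <- stats::rnorm(8, 0, effect_size)
    out <- data.frame(phenotype = feat, marker = map$marker[mk], class = cls,
                      stringsAsFactors = FALSE)
    out[eff_cols] <- as.list(eff - mean(eff))
    out
  }
  rows <- c(lapply(cis_feats, add_row, cls = "cis"),
            lapply(trans_feats, add_row, cls = "trans"))
  if (length(rows) == 0) {
    qtl <- data.frame(phenotype = character(), marker = character(),
                      class = character(), stringsAsFactors = FALSE)
    for (cc in eff_cols) qtl[[cc]] <- numeric(0)
    return(qtl)
  }
  do.call(rbind, rows)
}

#' @export
print.do_dataset <- function(x, ...) {
  cat(sprintf("Synthetic DO dataset: %d individuals, %d markers on %d chromosomes\n",
              dim(x$probs)[1], dim(x$probs)[2], nrow(x$config$chromosomes)))
  cat(sprintf("  features: %d mRNA, %d miRNA; planted QTL: %d\n",
              sum(x$annot$class == "mrna"), sum(x$annot$class == "mirna"),
              nrow(x$truth$qtl)))
  cat(sprintf("  diets: %s\n", paste(capture_table(x$covar$diet), collapse = ", ")))
  invisible(x)
}

capture_table <- function(f) {
  tb <- table(f)
  sprintf("%s=%d", names(tb), as.integer(tb))
}
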