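# Permutation-based per-phenotype significance thresholds: full nulls and
# the two-stage 50-permutation screen.

#' Permutation configuration
#'
#' @param n_perm_full Permutations for the full null (default 1000).
#' @param n_perm_screen Permutations for the screening stage (default 50).
#' @param final_quantile Quantile of the full null used as the individual
#'   significance threshold (default 0.95).
#' @param screen_quantile Quantile used in the screen before subtracting
#'   the quantile SE (default 0.90).
#' @param se_method Quantile standard-error estimator for the screen:
#'   `"maritz_jarrett"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap resamples when `se_method = "bootstrap"`.
#' @param seed Master seed; per-phenotype permutation streams are derived
#'   from it by stable hashing, so adding phenotypes never changes
#'   existing nulls.
#' @return Object of class `perm_config`.
#' @export
perm_config <- function(n_perm_full = 1000L, n_perm_screen = 50L,
                        final_quantile = 0.95, screen_quantile = 0.90,
                        se_method = c("maritz_jarrett", "bootstrap"),
                        n_boot = 200L, seed = 1L) {
  n_perm_full <- check_count(n_perm_full, "n_perm_full", min = 2L)
  n_perm_screen <- check_count(n_perm_screen, "n_perm_screen", min = 2L)
  check_prob(final_quantile, "final_quantile", lo_open = TRUE, hi_open = TRUE)
  check_prob(screen_quantile, "screen_quantile", lo_open = TRUE, hi_open = TRUE)
  if (screen_quantile >= final_quantile)
    stopf("screen_quantile must be below final_quantile")
  structure(list(n_perm_full = n_perm_full, n_perm_screen = n_perm_screen,
                 final_quantile = final_quantile,
                 screen_quantile = screen_quantile,
                 se_method = match.arg(se_method),
                 n_boot = check_count(n_boot, "n_boot", min = 10L),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "perm_config")
}

#' Genome-wide max-LOD permutation null for each phenotype
#'
#' Shuffles phenotype rows jointly against genotype, covariates and
#' kinship, rescans, and records the genome-wide maximum LOD.  The null
#' variance components are estimated once per (phenotype, chromosome)
#' from the observed data and held fixed across permutations; the
#' whitened marker projections are precomputed, so each permutation costs
#' one set of matrix-vector products.
#'
#' @inheritParams qtl_scan
#' @param n_perm Number of permutations (>= 2).
#' @param seed Master seed (per-phenotype streams derived by
#'   [hash_seed()]).
#' @return Matrix of max-LOD draws, `n_perm` x phenotypes.
#' @export
scan_permute <- function(probs, pheno, kinship = NULL, addcovar = NULL,
                         intcovar = NULL, map = attr(probs, "map"),
                         n_perm = 1000L, seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm", min = 2L)
  pheno <- as_pheno_matrix(pheno)
  n <- dim(probs)[1]
  X0 <- build_covar(addcovar, n)
  chroms <- unique(map$chrom)
  eigs <- loco_eigens(kinship, map, n)
  draws <- matrix(NA_real_, n_perm, ncol(pheno),
                  dimnames = list(NULL, colnames(pheno)))
  for (phj in seq_len(ncol(pheno))) {
    y <- pheno[, phj]
    if (stats::var(y) < 1e-14 * max(1, mean(y)^2)) {
      draws[, phj] <- 0
      next
    }
    ctxs <- lapply(chroms, function(cc) {
      idx <- which(map$chrom == cc)
      chrom_scan_ctx(probs[, idx, , drop = FALSE], y, X0, eigs[[cc]], intcovar)
    })
    with_seed(hash_seed(seed, colnames(pheno)[phj]), {
      for (k in seq_len(n_perm)) {
        yp <- y[sample.int(n)]
        draws[k, phj] <- max(vapply(ctxs, function(ctx) max(ctx$lod_fun(yp)),
                                    numeric(1)))
      }
    })
  }
  draws
}

#' Empirical LOD threshold from null draws
#'
#' Linear-interpolation (type 7) empirical quantile of a vector of
#' genome-wide max-LOD permutation draws.
#'
#' @param draws Numeric vector of max-LOD draws.
#' @param quantile Quantile level (default 0.95).
#' @return Single LOD threshold.
#' @export
perm_threshold <- function(draws, quantile = 0.95) {
  check_prob(quantile, "quantile", lo_open = TRUE, hi_open = TRUE)
  emp_quantile(draws, quantile)
}

#' Standard error of an empirical quantile
#'
#' Maritz-Jarrett kernel estimator (default) or a simple bootstrap.
#'
#' @param draws Numeric draws.
#' @param quantile Quantile level.
#' @param method `"maritz_jarrett"` or `"bootstrap"`.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return Single nonnegative SE.
#' @export
quantile_se <- function(draws, quantile = 0.90,
                        method = c("maritz_jarrett", "bootstrap"),
                        n_boot = 200L, seed = 1L) {
  method <- match.arg(method)
  n <- length(draws)
  if (n < 2L) stopf("need at least 2 draws")
  if (method == "maritz_jarrett") {
    x <- sort(draws)
    m <- max(1L, min(n, as.integer(floor(quantile * n + 0.5))))
    i <- seq_len(n)
    W <- stats::pbeta(i / n, m, n - m + 1) - stats::pbeta((i - 1) / n, m, n - m + 1)
    c1 <- sum(W * x)
    c2 <- sum(W * x^2)
    sqrt(max(c2 - c1^2, 0))
  } else {
    with_seed(seed, {
      stats::sd(vapply(seq_len(n_boot), function(b)
        emp_quantile(sample(draws, n, replace = TRUE), quantile), numeric(1)))
    })
  }
}

#' Two-stage permutation screen for per-phenotype thresholds
#'
#' Stage 1 runs a small permutation null (default 50) for every phenotype
#' and forms a conservative screen threshold: the 90th quantile minus its
#' quantile SE.  Phenotypes whose observed genome-wide max LOD exceeds the
#' screen threshold become candidates.  Stage 2 runs the full null
#' (default 1000) for the candidates only; a candidate is significant when
#' its observed max LOD exceeds the 95th-quantile full threshold.
#' Because per-phenotype permutation streams are seed-hashed, the stage-1
#' draws are the first `n_perm_screen` draws of the full stream and the
#' two-stage result can be compared against exhaustive full permutation.
#'
#' @inheritParams scan_permute
#' @param scan Optional precomputed `qtl_scan` for the observed data (a
#'   scan is run if omitted).
#' @param config A [perm_config()].
#' @return Object of class `two_stage_result`: `thresholds` data frame
#'   (phenotype, stage, n_perm, threshold, quantile_se, max_lod,
#'   candidate, significant), `candidates`, `significant`, and the
#'   stage-2 `full_draws` matrix.
#' @export
two_stage_screen <- function(probs, pheno, kinship = NULL, addcovar = NULL,
                             intcovar = NULL, map = attr(probs, "map"),
                             config = perm_config(), scan = NULL) {
  stopifnot(inherits(config, "perm_config"))
  pheno <- as_pheno_matrix(pheno)
  if (is.null(scan))
    scan <- qtl_scan(probs, pheno, kinship, addcovar, intcovar, map)
  obs <- max_lod(scan)

  screen_draws <- scan_permute(probs, pheno, kinship, addcovar, intcovar,
                               map, n_perm = config$n_perm_screen,
                               seed = config$seed)
  q90 <- apply(screen_draws, 2, emp_quantile, q = config$screen_quantile)
  se <- apply(screen_draws, 2, quantile_se, quantile = config$screen_quantile,
              method = config$se_method, n_boot = config$n_boot,
              seed = config$seed)
  screen_thr <- q90 - se
  candidates <- colnames(pheno)[obs > screen_thr]

  full_draws <- NULL
  full_thr <- stats::setNames(rep(NA_real_, ncol(pheno)), colnames(pheno))
  if (length(candidates) > 0) {
    full_draws <- scan_permute(probs, pheno[, candidates, drop = FALSE],
                               kinship, addcovar, intcovar, map,
                               n_perm = config$n_perm_full,
                               seed = config$seed)
    full_thr[candidates] <- apply(full_draws, 2, emp_quantile,
                                  q = config$final_quantile)
  }
  significant <- candidates[obs[candidates] > full_thr[candidates]]

  thresholds <- data.frame(
    phenotype = colnames(pheno),
    stage = ifelse(colnames(pheno) %in% candidates, "full", "screen"),
    n_perm = ifelse(colnames(pheno) %in% candidates,
                    config$n_perm_full, config$n_perm_screen),
    threshold = ifelse(colnames(pheno) %in% candidates, full_thr, screen_thr),
    quantile_se = se,
    max_lod = obs,
    candidate = colnames(pheno) %in% candidates,
    significant = colnames(pheno) %in% significant,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(thresholds = thresholds, candidates = candidates,
                 significant = significant, full_draws = full_draws,
                 config = config),
            class = "two_stage_result")
}

#' @export
print.two_stage_result <- function(x, ...) {
  cat(sprintf("Two-stage permutation screen (%d -> %d permutations)\n",
              x$config$n_perm_screen, x$config$n_perm_full))
  cat(sprintf("  %d phenotypes, %d candidates, %d significant\n",
              nrow(x$thresholds), length(x$candidates), length(x$significant)))
  invisible(x)
}
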