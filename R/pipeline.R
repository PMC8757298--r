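# End-to-end pipeline: simulate/read -> four scans -> thresholds ->
# characterization -> architecture statistics -> plain-text outputs.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] describing the synthetic dataset (ignored
#'   when `input_dir` is given).
#' @param input_dir Optional directory in [write_dataset()] layout to read
#'   instead of simulating.
#' @param out_dir Output directory.
#' @param perm A [perm_config()]; the additive model gets the full
#'   permutation null for every phenotype, the interactive and
#'   diet-subset models the two-stage screen.
#' @param filters A [filter_config()].
#' @param window_mb Cis window (default 4).
#' @param drop LOD drop for support intervals (default 1.8).
#' @param models Model tags to run, a subset of
#'   `c("additive", "interactive", "hfca", "hp")`.
#' @param n_cis_qtl,n_trans_qtl,n_mirna_qtl Planted QTL counts passed to
#'   the generator.
#' @param h2,effect_size Generator parameters: target background
#'   heritability and founder-effect SD of planted QTL.
#' @param seed Master seed recorded in every output header.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            out_dir = tempfile("moqtl_run_"),
                            perm = perm_config(n_perm_full = 100L),
                            filters = filter_config(),
                            window_mb = 4.0, drop = 1.8,
                            models = c("additive", "interactive", "hfca", "hp"),
                            n_cis_qtl = 15L, n_trans_qtl = 5L,
                            n_mirna_qtl = 3L,
                            h2 = 0.3, effect_size = 0.75,
                            seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  if (!"additive" %in% models)
    stopf("the additive model anchors characterization and must be included")
  structure(list(sim = sim, input_dir = input_dir, out_dir = out_dir,
                 perm = perm, filters = filters, window_mb = window_mb,
                 drop = drop, models = models,
                 n_cis_qtl = n_cis_qtl, n_trans_qtl = n_trans_qtl,
                 n_mirna_qtl = n_mirna_qtl,
                 h2 = h2, effect_size = effect_size,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "pipeline_config")
}

#' eQTL category per feature from a QTL table
#'
#' "cis"/"trans" for features with exactly one peak, "multiple" for
#' multi-mapping features, "no-eQTL" otherwise.
#'
#' @param peaks A QTL table ([characterize_qtl()]).
#' @param features Character vector of all features.
#' @return Named character vector over `features`.
#' @export
eqtl_category <- function(peaks, features) {
  out <- stats::setNames(rep("no-eQTL", length(features)), features)
  if (nrow(peaks) > 0) {
    tb <- table(peaks$phenotype)
    multi <- names(tb)[tb > 1]
    single <- names(tb)[tb == 1]
    out[single] <- peaks$cis_trans[match(single, peaks$phenotype)]
    out[multi] <- "multiple"
  }
  out
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a dataset, runs the configured genome-scan models
#' (additive-diet, interactive-diet, and the two diet subsets),
#' determines per-phenotype permutation thresholds (full null for the
#' additive model, two-stage screen for the others), characterizes all
#' significant QTL, and computes the downstream architecture statistics:
#' differential expression by diet, miRNA-mRNA correlation structure,
#' eQTL-mirQTL colocalization, founder-allele enrichment, and the
#' allele-by-diet divergence ranking.  All tabular outputs are written
#' under `config$out_dir` with version/seed headers, plus a JSON run
#' manifest with per-file checksums.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages?
#' @return List of class `pipeline_result`: `dataset`, `scans`, `peaks`
#'   (per model), `thresholds`, `de`, `cor_structure`, `coloc`,
#'   `enrichment`, `diet_ranking`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  stages <- list()

  say("[simulate] building dataset")
  if (!is.null(config$input_dir)) {
    raw <- read_dataset(config$input_dir)
    expr <- raw$expr_native
    is_mirna <- raw$annot$class[match(rownames(expr), raw$annot$feature)] == "mirna"
    expr[is_mirna, ] <- log2(expr[is_mirna, , drop = FALSE] + 1)
    expr[!is_mirna, ] <- expr[!is_mirna, , drop = FALSE]
    dataset <- list(probs = raw$probs, map = raw$map, expr = expr,
                    expr_native = raw$expr_native, annot = raw$annot,
                    covar = raw$covar, truth = raw$truth,
                    config = config$sim)
    class(dataset) <- "do_dataset"
  } else {
    dataset <- simulate_do_dataset(config$sim,
                                   n_cis_qtl = config$n_cis_qtl,
                                   n_trans_qtl = config$n_trans_qtl,
                                   n_mirna_qtl = config$n_mirna_qtl,
                                   h2 = config$h2,
                                   effect_size = config$effect_size)
  }
  stages$simulate <- Sys.time()

  covar <- dataset$covar
  diet_ind <- matrix(as.numeric(covar$diet == levels(covar$diet)[2]),
                     dimnames = list(NULL, "diet"))
  pheno <- t(dataset$expr)  # individuals x features, analysis scale
  hfca_sel <- covar$diet == levels(covar$diet)[2]
  kin <- calc_kinship(dataset$probs, dataset$map)

  say("[scan] %d phenotypes, models: %s", ncol(pheno),
      paste(config$models, collapse = ", "))
  model_inputs <- list(
    additive = list(sel = TRUE, addcovar = diet_ind, intcovar = NULL),
    interactive = list(sel = TRUE, addcovar = diet_ind, intcovar = diet_ind),
    hfca = list(sel = hfca_sel, addcovar = NULL, intcovar = NULL),
    hp = list(sel = !hfca_sel, addcovar = NULL, intcovar = NULL)
  )
  scans <- list(); thresholds <- list(); peaks <- list()
  for (mdl in config$models) {
    mi <- model_inputs[[mdl]]
    sel <- if (isTRUE(mi$sel)) rep(TRUE, nrow(pheno)) else mi$sel
    probs_m <- dataset$probs[sel, , , drop = FALSE]
    attr(probs_m, "map") <- dataset$map
    kin_m <- if (all(sel)) kin else calc_kinship(probs_m, dataset$map)
    addc <- if (is.null(mi$addcovar)) NULL else mi$addcovar[sel, , drop = FALSE]
    intc <- if (is.null(mi$intcovar)) NULL else mi$intcovar[sel, , drop = FALSE]
    sc <- qtl_scan(probs_m, pheno[sel, , drop = FALSE], kin_m,
                   addcovar = addc, intcovar = intc, map = dataset$map,
                   model = mdl)
    say("[permute] %s model", mdl)
    if (mdl == "additive") {
      draws <- scan_permute(probs_m, pheno[sel, , drop = FALSE], kin_m,
                            addcovar = addc, intcovar = intc,
                            map = dataset$map,
                            n_perm = config$perm$n_perm_full,
                            seed = config$perm$seed)
      thr <- apply(draws, 2, perm_threshold,
                   quantile = config$perm$final_quantile)
      thr_df <- data.frame(phenotype = names(thr), stage = "full",
                           n_perm = config$perm$n_perm_full,
                           threshold = unname(thr), quantile_se = NA_real_,
                           stringsAsFactors = FALSE)
    } else {
      ts <- two_stage_screen(probs_m, pheno[sel, , drop = FALSE], kin_m,
                             addcovar = addc, intcovar = intc,
                             map = dataset$map, config = config$perm,
                             scan = sc)
      thr <- stats::setNames(ts$thresholds$threshold, ts$thresholds$phenotype)
      # non-candidates keep their (conservative) screen threshold
      thr_df <- ts$thresholds[, c("phenotype", "stage", "n_perm",
                                  "threshold", "quantile_se")]
    }
    thr <- pmax(thr, 1e-6)
    say("[characterize] %s model", mdl)
    pk <- characterize_qtl(sc, pheno[sel, , drop = FALSE], probs_m, thr,
                           dataset$annot, kinship = kin_m, addcovar = addc,
                           window_mb = config$window_mb, drop = config$drop)
    scans[[mdl]] <- sc; thresholds[[mdl]] <- thr_df; peaks[[mdl]] <- pk
  }
  stages$scan <- Sys.time()

  say("[architecture] differential expression, correlations, colocalization")
  mrna_sel <- dataset$annot$class == "mrna"
  de_mrna <- differential_expression(
    dataset$expr_native[mrna_sel, , drop = FALSE], covar$diet,
    floor = config$filters$mrna_floor,
    prevalence = config$filters$mrna_prevalence)
  de_mirna <- differential_expression(
    dataset$expr_native[!mrna_sel, , drop = FALSE], covar$diet,
    floor = config$filters$mirna_floor,
    prevalence = config$filters$mirna_prevalence)

  add_pk <- peaks$additive
  cat_all <- eqtl_category(add_pk[add_pk$class == "mrna", , drop = FALSE],
                           dataset$annot$feature[mrna_sel])
  cors <- correlation_structure(
    dataset$expr[!mrna_sel, , drop = FALSE],
    dataset$expr[mrna_sel, , drop = FALSE],
    eqtl_category = cat_all,
    multi_mapping = names(cat_all)[cat_all == "multiple"])
  coloc <- colocalize(add_pk[add_pk$class == "mrna", , drop = FALSE],
                      add_pk[add_pk$class == "mirna", , drop = FALSE])
  enrich <- NULL
  if (nrow(add_pk) >= 2) {
    enrich <- founder_enrichment(
      as.matrix(add_pk[, paste0("eff_", names(do_founders))]))
  }
  ranking <- NULL
  if (all(c("interactive", "hfca", "hp") %in% config$models)) {
    ranking <- allele_diet_ranking(
      peaks$interactive[peaks$interactive$class == "mrna", , drop = FALSE],
      peaks$hfca, peaks$hp, pheno, dataset$probs, covar$diet)
  }
  stages$architecture <- Sys.time()

  say("[write] outputs -> %s", config$out_dir)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  sd <- config$seed
  outputs <- character()
  emit <- function(obj, name) {
    p <- file.path(config$out_dir, name)
    write_qtl_tsv(obj, p, sd, hash)
    outputs <<- c(outputs, p)
  }
  for (mdl in config$models) {
    emit(scans[[mdl]], sprintf("lod_%s.tsv", mdl))
    emit(thresholds[[mdl]], sprintf("thresholds_%s.tsv", mdl))
    emit(peaks[[mdl]], sprintf("qtl_%s.tsv", mdl))
  }
  emit(de_mrna, "de_mrna.tsv")
  emit(de_mirna, "de_mirna.tsv")
  emit(cors$records[cors$records$significant, , drop = FALSE],
       "correlations_significant.tsv")
  emit(coloc, "colocalization.tsv")
  if (!is.null(ranking)) emit(ranking, "diet_interaction_ranking.tsv")

  manifest <- list(
    version = pkg_version(),
    seed = sd,
    config_hash = unname(hash),
    config = unclass_deep(config),
    stages = lapply(stages, format, usetz = TRUE),
    started = format(t0, usetz = TRUE),
    finished = format(Sys.time(), usetz = TRUE),
    checksums = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(dataset = dataset, scans = scans, thresholds = thresholds,
                 peaks = peaks, de = list(mrna = de_mrna, mirna = de_mirna),
                 cor_structure = cors, coloc = coloc, enrichment = enrich,
                 diet_ranking = ranking, manifest = manifest,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("moqtl pipeline run\n")
  for (mdl in names(x$peaks)) {
    pk <- x$peaks[[mdl]]
    cat(sprintf("  %-11s %3d QTL (%d cis, %d trans)\n", mdl, nrow(pk),
                sum(pk$cis_trans == "cis"), sum(pk$cis_trans == "trans")))
  }
  cat(sprintf("  DE: %d/%d mRNA, %d/%d miRNA significant\n",
              sum(x$de$mrna$significant), sum(x$de$mrna$filtered_in),
              sum(x$de$mirna$significant), sum(x$de$mirna$filtered_in)))
  cat(sprintf("  correlations: %d significant of %d\n",
              x$cor_structure$n_significant, x$cor_structure$n_pairs))
  cat(sprintf("  outputs: %s\n", x$config$out_dir))
  invisible(x)
}
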