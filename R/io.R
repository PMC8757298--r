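# Plain-text interchange: TSV tables (single header row, '#' comment
# header lines carrying version/seed/config hash), long-format
# allele-probability tensor, JSON ground truth.

pkg_version <- function() as.character(utils::packageVersion("moqtl"))

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass_deep(config), tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep)
  else if (is.factor(x)) as.character(x)
  else unclass(x)
}

write_tsv <- function(df, path, seed = NA, hash = NA) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# moqtl %s; seed=%s; config=%s", pkg_version(),
                     seed, hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits `markers.tsv`, `alleleprobs.tsv` (long format: marker, id, one
#' column per founder), `expr_mrna.tsv` and `expr_mirna.tsv` (native
#' scales, features x individuals), `annot.tsv`, `covar.tsv` and
#' `truth.json`.  Every table carries a header comment with package
#' version, seed and config hash.
#'
#' @param dataset A [simulate_do_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "do_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- dataset$config$seed
  hash <- config_hash(dataset$config)
  write_tsv(dataset$map, file.path(dir, "markers.tsv"), seed, hash)

  n <- dim(dataset$probs)[1]; M <- dim(dataset$probs)[2]
  long <- data.frame(
    marker = rep(dimnames(dataset$probs)[[2]], each = n),
    id = rep(dimnames(dataset$probs)[[1]], times = M),
    stringsAsFactors = FALSE)
  for (f in seq_len(8))
    long[[names(do_founders)[f]]] <- as.vector(dataset$probs[, , f])
  write_tsv(long, file.path(dir, "alleleprobs.tsv"), seed, hash)

  for (cls in c("mrna", "mirna")) {
    rowsel <- dataset$annot$class == cls
    if (!any(rowsel)) next
    m <- dataset$expr_native[rowsel, , drop = FALSE]
    df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_tsv(df, file.path(dir, sprintf("expr_%s.tsv", cls)), seed, hash)
  }
  write_tsv(dataset$annot, file.path(dir, "annot.tsv"), seed, hash)
  write_tsv(dataset$covar, file.path(dir, "covar.tsv"), seed, hash)
  jsonlite::write_json(
    list(qtl = dataset$truth$qtl, phenotypes = dataset$truth$phenotypes,
         seed = seed, version = pkg_version()),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a dataset directory back into aligned objects
#'
#' Individuals are aligned across all tables by their shared ids (the
#' covariate table order is canonical); mismatched, duplicated or missing
#' ids and malformed positions raise descriptive errors.
#'
#' @param dir Directory written by [write_dataset()] (or following the
#'   same layout).
#' @return List: `probs` (with `"map"` attribute), `map`, `expr_native`,
#'   `annot`, `covar`, `truth` (NULL if absent).
#' @export
read_dataset <- function(dir) {
  covar <- read_tsv(file.path(dir, "covar.tsv"))
  if (!all(c("id", "diet") %in% names(covar)))
    stopf("covar.tsv must have columns id, diet")
  if (anyDuplicated(covar$id))
    stopf("duplicated individual id(s): %s",
          paste(unique(covar$id[duplicated(covar$id)]), collapse = ", "))
  covar$diet <- factor(covar$diet, levels = unique(covar$diet))
  ids <- covar$id

  map <- read_tsv(file.path(dir, "markers.tsv"), colClasses = c(chrom = "character"))
  if (!all(c("marker", "chrom", "pos_mb") %in% names(map)))
    stopf("markers.tsv must have columns marker, chrom, pos_mb")
  if (any(!is.finite(map$pos_mb))) stopf("non-finite marker position(s)")

  long <- read_tsv(file.path(dir, "alleleprobs.tsv"))
  miss <- setdiff(ids, unique(long$id))
  if (length(miss) > 0)
    stopf("individual(s) absent from alleleprobs: %s", paste(miss, collapse = ", "))
  extra <- setdiff(unique(long$id), ids)
  if (length(extra) > 0)
    stopf("individual(s) absent from covariates: %s", paste(extra, collapse = ", "))
  n <- length(ids); M <- nrow(map)
  probs <- array(NA_real_, c(n, M, 8),
                 dimnames = list(ids, map$marker, names(do_founders)))
  ii <- match(long$id, ids)
  mm <- match(long$marker, map$marker)
  if (any(is.na(mm))) stopf("alleleprobs references unknown marker(s)")
  for (f in seq_len(8))
    probs[cbind(ii, mm, f)] <- long[[names(do_founders)[f]]]
  if (any(is.na(probs))) stopf("incomplete allele-probability tensor")
  attr(probs, "map") <- map

  annot <- read_tsv(file.path(dir, "annot.tsv"), colClasses = c(chrom = "character"))
  expr <- NULL
  for (cls in c("mrna", "mirna")) {
    path <- file.path(dir, sprintf("expr_%s.tsv", cls))
    if (!file.exists(path)) next
    df <- read_tsv(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$feature
    miss <- setdiff(ids, colnames(m))
    if (length(miss) > 0)
      stopf("individual(s) absent from expr_%s: %s", cls,
            paste(miss, collapse = ", "))
    expr <- rbind(expr, m[, ids, drop = FALSE])
  }
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    tr <- jsonlite::read_json(tj, simplifyVector = TRUE)
    truth <- ground_truth(as.data.frame(tr$qtl), as.data.frame(tr$phenotypes))
  }
  list(probs = probs, map = map, expr_native = expr, annot = annot,
       covar = covar, truth = truth)
}

#' Write a QTL table / thresholds table / LOD matrix as TSV
#'
#' @param x Object to write (`qtl_peaks` data frame, thresholds data
#'   frame, or `qtl_scan` whose LOD matrix is written markers x
#'   phenotypes).
#' @param path Output file.
#' @param seed,hash Optional header metadata.
#' @return `path`, invisibly.
#' @export
write_qtl_tsv <- function(x, path, seed = NA, hash = NA) {
  if (inherits(x, "qtl_scan")) {
    df <- data.frame(marker = rownames(x$lod), x$lod, check.names = FALSE,
                     stringsAsFactors = FALSE)
    return(write_tsv(df, path, seed, hash))
  }
  write_tsv(as.data.frame(x), path, seed, hash)
}
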