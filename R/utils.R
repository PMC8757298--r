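# Internal helpers: argument checks, seeding, small numerics.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_prob <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) stopf("`%s` must be in %s%g, %g%s", name,
                 if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]")
  as.numeric(x)
}

#' Derive a stable per-phenotype random seed from a master seed
#'
#' Hashes a phenotype name into a 31-bit integer offset so that each
#' phenotype's permutation null is reproducible and independent of which
#' other phenotypes are present in the panel.
#'
#' @param master_seed Integer master seed.
#' @param name Character scalar (e.g. a phenotype id).
#' @return A single integer seed in `[0, 2^31)`.
#' @export
hash_seed <- function(master_seed, name) {
  stopifnot(length(name) == 1L, is.character(name))
  h <- 0
  for (cc in utf8ToInt(name)) h <- (h * 31 + cc) %% 2147480009
  as.integer((as.numeric(master_seed) %% 2147480009 * 2654435 + h) %% 2147480009)
}

# Evaluate expr with a local RNG state seeded by `seed`, restoring the
# caller's RNG afterwards so generator sub-streams do not interfere.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Linear-interpolation empirical quantile (type 7), shared convention for
# all permutation thresholds.
emp_quantile <- function(x, q) {
  if (length(x) == 0L) stopf("empty draw vector")
  unname(stats::quantile(x, probs = q, type = 7, names = FALSE))
}
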