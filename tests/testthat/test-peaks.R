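# Peak finding, support intervals, cis/trans calls, variance explained.

make_scan <- function(lod, map, model = "additive") {
  structure(list(lod = lod, map = map, model = model,
                 hsq = matrix(0, ncol(lod), length(unique(map$chrom))),
                 n = 100),
            class = "qtl_scan")
}

two_chrom_map <- function(m = 5) {
  data.frame(marker = sprintf("m%02d", 1:(2 * m)),
             chrom = rep(c("1", "2"), each = m),
             pos_mb = rep(seq_len(m), 2), stringsAsFactors = FALSE)
}

test_that("find_peaks takes at most one peak per chromosome, strictly above threshold", {
  map <- two_chrom_map()
  lod <- matrix(c(1, 2, 3, 2, 1, 0, 1, 9, 1, 0), ncol = 1,
                dimnames = list(map$marker, "p1"))
  sc <- make_scan(lod, map)
  expect_equal(nrow(find_peaks(sc, 10)), 0)          # everything below
  pk <- find_peaks(sc, 2.5)
  expect_equal(nrow(pk), 2)                          # multiple mappings
  expect_equal(pk$marker, c("m03", "m08"))
  # flat curve exactly at the threshold: strict inequality excludes it
  lodf <- matrix(rep(4, 10), ncol = 1, dimnames = list(map$marker, "p1"))
  expect_equal(nrow(find_peaks(make_scan(lodf, map), 4)), 0)
  # ties broken by smallest position
  lodt <- matrix(c(1, 5, 5, 1, 1, 0, 0, 0, 0, 0), ncol = 1,
                 dimnames = list(map$marker, "p1"))
  expect_equal(find_peaks(make_scan(lodt, map), 2)$marker, "m02")
})

test_that("support intervals follow the first-at-or-below walk from the peak", {
  lod <- c(1, 3, 8, 3, 1); pos <- 1:5
  ci <- support_interval(lod, pos, 3, drop = 1.8)
  expect_equal(c(ci$lo, ci$hi), c(2, 4))
  # plateau never dropping 1.8: censored at the chromosome ends
  ci2 <- support_interval(c(5, 5.5, 6, 5.5, 5.2), pos, 3, drop = 1.8)
  expect_equal(c(ci2$lo, ci2$hi), c(1, 5))
  # degenerate drop collapses onto the peak marker
  ci3 <- support_interval(lod, pos, 3, drop = 0)
  expect_equal(c(ci3$lo, ci3$hi), c(3, 3))
})

test_that("cis/trans classification respects the window and chromosome", {
  expect_equal(classify_peak("1", 10.0, "1", 13.9, 4), "cis")
  expect_equal(classify_peak("1", 10.0, "1", 14.5, 4), "trans")
  expect_equal(classify_peak("2", 10.0, "7", 10.0, 4), "trans")
  expect_equal(classify_peak("1", 10.0, "1", 14.0, 4), "cis")  # inclusive
  expect_error(classify_peak("1", 1, NA, 1, 4), "TSS")
  # shrinking the window can only move calls cis -> trans
  set.seed(77)
  for (i in 1:50) {
    pk <- runif(1, 0, 100); ts <- runif(1, 0, 100)
    c4 <- classify_peak("1", pk, "1", ts, 4)
    c1 <- classify_peak("1", pk, "1", ts, 1)
    if (c4 == "trans") expect_equal(c1, "trans")
  }
})

test_that("variance explained matches a two-regression oracle and is in [0,1]", {
  probs <- random_probs(8, 3, seed = 41)
  set.seed(42)
  y <- rnorm(8)
  x <- rnorm(8)
  ve <- variance_explained(probs, "m002", y, addcovar = cbind(x = x))
  r2 <- function(X) {
    f <- lm.fit(X, y); 1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  oracle <- r2(cbind(1, x, probs[, 2, ])) - r2(cbind(1, x))
  expect_equal(ve, oracle, tolerance = 1e-10)
  expect_gte(ve, 0)

  # exact linear function of one founder dosage: everything explained
  yy <- probs[, 1, "C"] * 2 + 1
  expect_gt(variance_explained(probs, "m001", yy), 0.999)

  # independent traits: small at n = 300
  probs2 <- random_probs(300, 4, seed = 43)
  set.seed(44)
  ves <- replicate(20, variance_explained(probs2, "m001", rnorm(300)))
  expect_lte(median(ves), 0.08)
})

test_that("characterize_qtl assembles a complete peak table on a planted panel", {
  cfg <- tiny_config(n = 150, n_mrna = 15, n_mirna = 4, seed = 61, markers = 25L)
  ds <- simulate_do_dataset(cfg, n_cis_qtl = 4, n_trans_qtl = 2, n_mirna_qtl = 1,
                            effect_size = 1.2, h2 = 0.25)
  kin <- calc_kinship(ds$probs, ds$map)
  pheno <- t(ds$expr)
  diet <- matrix(as.numeric(ds$covar$diet == "HFCA"), dimnames = list(NULL, "diet"))
  sc <- qtl_scan(ds$probs, pheno, kin, addcovar = diet)
  tab <- characterize_qtl(sc, pheno, ds$probs, threshold = 7, annot = ds$annot,
                          kinship = kin, addcovar = diet)
  expect_s3_class(tab, "qtl_peaks")
  expect_true(all(tab$lod > tab$threshold))
  expect_true(all(tab$ci_lo <= tab$peak_mb & tab$peak_mb <= tab$ci_hi))
  expect_true(all(tab$var_explained >= 0 & tab$var_explained <= 1))
  expect_true(all(tab$h2 >= 0 & tab$h2 <= 1))
  expect_true(all(tab$cis_trans %in% c("cis", "trans")))
  expect_true(all(is.finite(as.matrix(tab[paste0("eff_", names(do_founders))]))))

  # detected planted QTL carry the planted class
  qtl <- ds$truth$qtl
  det <- tab[tab$phenotype %in% qtl$phenotype, ]
  for (i in seq_len(nrow(det))) {
    truth_cls <- qtl$class[qtl$phenotype == det$phenotype[i] &
                             qtl$marker %in%
                               ds$map$marker[ds$map$chrom == det$chrom[i]]]
    if (length(truth_cls) == 1) expect_equal(det$cis_trans[i], truth_cls)
  }
})
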