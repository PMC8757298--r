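# Mixed-model genome scan: LOD oracle equivalence, nesting, recovery.

test_that("with zero kinship the LOD equals the closed-form least-squares oracle", {
  # hand-chosen n = 8 instance with a diallelic-like marker pattern
  h <- matrix(rep(c(1L, 6L), each = 4), 8, 1)
  probs <- probs_from_homologs(h, h)
  y <- c(1.2, 0.8, 1.1, 0.9, 3.0, 3.2, 2.9, 3.1)
  sc <- qtl_scan(probs, y, kinship = NULL)
  Z <- probs[, 1, ]
  rss0 <- sum(lm.fit(matrix(1, 8, 1), y)$residuals^2)
  rss1 <- sum(lm.fit(cbind(1, Z), y)$residuals^2)
  expect_equal(unname(sc$lod[1, 1]), 8 / 2 * log10(rss0 / rss1), tolerance = 1e-10)
})

test_that("a constant phenotype yields zero LOD everywhere with a warning", {
  probs <- random_probs(30, 10, seed = 3)
  expect_warning(sc <- qtl_scan(probs, rep(2.5, 30), kinship = NULL), "constant")
  expect_true(all(sc$lod == 0))
})

test_that("LOD is nonnegative, finite, and deterministic; interactive nests additive", {
  probs <- random_probs(100, 24, seed = 7)
  kin <- calc_kinship(probs)
  set.seed(41)
  y <- rnorm(100)
  d <- matrix(rep(0:1, 50), dimnames = list(NULL, "diet"))
  sc_add <- qtl_scan(probs, y, kin, addcovar = d)
  sc_int <- qtl_scan(probs, y, kin, addcovar = d, intcovar = d)
  expect_true(all(is.finite(sc_add$lod)) && all(sc_add$lod >= 0))
  expect_true(all(is.finite(sc_int$lod)) && all(sc_int$lod >= 0))
  # same null, larger full model: interactive LOD >= additive LOD marker-wise
  expect_true(all(sc_int$lod - sc_add$lod >= -1e-8))
  # no randomness in fitting
  sc_add2 <- qtl_scan(probs, y, kin, addcovar = d)
  expect_identical(sc_add$lod, sc_add2$lod)
})

test_that("scan LODs are invariant to reshuffling focal-chromosome markers inside the kinship", {
  probs <- random_probs(60, 20, seed = 12, chroms = 2)
  map <- attr(probs, "map")
  set.seed(5)
  y <- rnorm(60)
  kin <- calc_kinship(probs, map)
  # rebuild the kinship after replacing chromosome-1 marker content:
  # LOCO means chromosome-1 LODs cannot depend on it
  idx <- which(map$chrom == "1")
  probs_k <- probs
  probs_k[, idx, ] <- random_probs(60, 20, seed = 888, chroms = 2)[, idx, ]
  attr(probs_k, "map") <- map
  kin2 <- calc_kinship(probs_k, map)
  sc1 <- qtl_scan(probs, y, kin, map = map)
  sc2 <- qtl_scan(probs, y, kin2, map = map)
  # equal up to floating-point accumulation in the kinship assembly
  expect_equal(sc1$lod[idx, 1], sc2$lod[idx, 1], tolerance = 1e-6)
  expect_false(isTRUE(all.equal(sc1$lod[-idx, 1], sc2$lod[-idx, 1])))
})

test_that("a strong planted QTL is recovered at or next to the planted marker", {
  hits <- 0
  for (r in 1:20) {
    probs <- random_probs(200, 30, seed = 100 + r)
    map <- attr(probs, "map")
    covar <- data.frame(id = dimnames(probs)[[1]],
                        diet = factor(rep(c("HP", "HFCA"), 100),
                                      levels = c("HP", "HFCA")))
    set.seed(200 + r)
    eff <- rnorm(8, 0, 1.4)
    tr <- single_qtl_truth("p1", map$marker[12], eff - mean(eff), "1",
                           map$pos_mb[12], h2 = 0.1)
    y <- simulate_expression(probs, tr, covar, seed = 300 + r)[1, ]
    kin <- calc_kinship(probs, map)
    sc <- qtl_scan(probs, y, kin)
    peak <- which.max(sc$lod[, 1])
    if (abs(peak - 12) <= 1) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("scan summary and max_lod agree", {
  probs <- random_probs(50, 12, seed = 9)
  set.seed(2); y <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("a", "b")))
  sc <- qtl_scan(probs, y, kinship = NULL)
  sm <- summary(sc)
  ml <- max_lod(sc)
  expect_equal(sort(sm$lod, decreasing = TRUE), sort(unname(ml), decreasing = TRUE))
})
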