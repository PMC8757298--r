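# Synthetic DO generator: mosaics, allele probabilities, expression.

test_that("zero recombination rate yields single-founder homologs per chromosome", {
  cfg <- tiny_config(n = 20, recomb_rate = 0, seed = 3)
  mos <- simulate_mosaics(cfg)
  for (cc in c("1", "2")) {
    idx <- mos$map$chrom == cc
    expect_true(all(apply(mos$h1[, idx], 1, function(x) length(unique(x))) == 1))
    expect_true(all(apply(mos$h2[, idx], 1, function(x) length(unique(x))) == 1))
  }
  expect_true(all(mos$n_events == 0))
})

test_that("switch events match a brute-force Monte-Carlo of the same Markov process", {
  # 1000 individuals x 2 homologs on one 100-Mb chromosome at 0.05/Mb:
  # expected 5 switch events per homolog
  cfg <- sim_config(n_individuals = 1000,
                    chromosomes = data.frame(chrom = "1", length_mb = 100,
                                             n_markers = 40L),
                    recomb_rate = 0.05, n_mrna = 1, n_mirna = 0, seed = 11)
  mos <- simulate_mosaics(cfg)
  # independent oracle: event counts of a Poisson switch process
  set.seed(99)
  oracle <- rpois(20000, 0.05 * 100)
  se <- sd(oracle) / sqrt(length(mos$n_events))
  expect_lt(abs(mean(mos$n_events) - 5.0), 3 * se + 3 * sd(oracle) / sqrt(20000))
})

test_that("founder marginals are near 1/8 and mosaics are seed-deterministic", {
  cfg <- tiny_config(n = 400, seed = 5)
  mos <- simulate_mosaics(cfg)
  counts <- table(factor(c(mos$h1, mos$h2), levels = 1:8))
  freq <- counts / sum(counts)
  # conservative binomial band using only the 800 homologs at one locus
  se <- sqrt(0.125 * 0.875 / 800)
  expect_true(all(abs(freq - 0.125) < 3 * se))

  mos2 <- simulate_mosaics(tiny_config(n = 400, seed = 5))
  expect_identical(mos, mos2)
  mos3 <- simulate_mosaics(tiny_config(n = 400, seed = 6))
  expect_false(identical(mos$h1, mos3$h1))
})

test_that("allele probabilities encode homologs with softening and sum to one", {
  h1 <- matrix(6L, 2, 3)  # CAST
  h2 <- matrix(c(6L, 6L, 6L, 7L, 7L, 7L), 2, 3, byrow = TRUE)  # CAST / PWK
  probs <- probs_from_homologs(h1, h2)
  # homozygous CAST, no softening
  expect_equal(unname(probs[1, 1, "F"]), 1.0)
  expect_equal(unname(sum(probs[1, 1, -6])), 0.0)
  # heterozygous CAST/PWK
  expect_equal(unname(probs[2, 1, "F"]), 0.5)
  expect_equal(unname(probs[2, 1, "G"]), 0.5)

  cfg <- tiny_config(n = 30, seed = 2)
  mos <- simulate_mosaics(cfg)
  soft <- mosaics_to_alleleprobs(mos, softening = 0.02)
  sums <- apply(soft, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # softened mass: true homozygote has 0.98 + 0.02/8
  expect_true(all(soft >= 0.02 / 8 - 1e-15))
  expect_error(mosaics_to_alleleprobs(mos, softening = 0.6), "softening")
})

test_that("null traits are uncorrelated with dosages; noise-free QTL is exactly linear", {
  probs <- random_probs(200, 30, seed = 8)
  map <- attr(probs, "map")
  covar <- data.frame(id = dimnames(probs)[[1]],
                      diet = factor(rep(c("HP", "HFCA"), 100),
                                    levels = c("HP", "HFCA")))
  # pure-noise trait: h2 = 0, no QTL, no diet effect
  tr0 <- single_qtl_truth("p1", map$marker[1], rep(0, 8), "1", 10)
  y0 <- simulate_expression(probs, tr0, covar, seed = 21)[1, ]
  cors <- abs(suppressWarnings(
    cor(y0, matrix(probs, nrow = 200))))  # every (marker, founder) dosage
  expect_gte(mean(cors < 0.2, na.rm = TRUE), 0.95)

  # noise-free planted QTL: exact linear function of the dosage block
  eff <- c(2, 0, 0, 0, 0, -1, 0, 0)
  tr1 <- single_qtl_truth("p1", map$marker[5], eff, "1", 10, background_sd = 0)
  y1 <- simulate_expression(probs, tr1, covar, seed = 22)[1, ]
  Z <- probs[, 5, ]
  fit <- lm.fit(cbind(1, Z), y1)
  expect_lt(sum(fit$residuals^2), 1e-20)
})

test_that("datasets are byte-identical under a fixed seed and QTL are planted as labelled", {
  cfg <- tiny_config(n = 40, n_mrna = 12, seed = 9)
  d1 <- simulate_do_dataset(cfg, n_cis_qtl = 3, n_trans_qtl = 2)
  d2 <- simulate_do_dataset(cfg, n_cis_qtl = 3, n_trans_qtl = 2)
  expect_identical(d1$expr, d2$expr)
  expect_identical(d1$probs, d2$probs)
  expect_identical(d1$truth, d2$truth)

  qtl <- d1$truth$qtl
  ph <- d1$truth$phenotypes
  for (i in seq_len(nrow(qtl))) {
    mi <- match(qtl$marker[i], d1$map$marker)
    ti <- match(qtl$phenotype[i], ph$phenotype)
    same_chr <- d1$map$chrom[mi] == ph$chrom[ti]
    near <- same_chr && abs(d1$map$pos_mb[mi] - ph$tss_mb[ti]) <= 4
    if (qtl$class[i] == "cis") expect_true(near) else expect_false(near)
  }
  # effect vectors are mean-centered
  eff <- as.matrix(qtl[, paste0("eff_", names(do_founders))])
  expect_true(all(abs(rowMeans(eff)) < 1e-12))
})

test_that("config validation rejects malformed inputs", {
  expect_error(tiny_config(n = 4), "n_individuals")
  expect_error(sim_config(chromosomes = data.frame(chrom = "1", length_mb = -5,
                                                   n_markers = 10L)),
               "positive")
  expect_error(sim_config(chromosomes = data.frame(chrom = "1", length_mb = 50,
                                                   n_markers = 1L)),
               "at least 2")
  probs <- random_probs(10, 5)
  covar <- data.frame(id = 1:9, diet = factor(rep(c("a", "b"), length.out = 9)))
  tr <- single_qtl_truth("p1", "m001", rep(0, 8), "1", 1)
  expect_error(simulate_expression(probs, tr, covar, seed = 1), "mismatch")
})
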