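# Architecture statistics: enrichment, colocalization, correlations,
# Fisher tables, differential expression, diet-interaction ranking.

test_that("founder effect scaling centers every peak and Dunn matches a manual z", {
  set.seed(50)
  eff <- matrix(rnorm(40 * 8), 40, 8)
  fe <- founder_enrichment(eff)
  expect_true(all(abs(rowSums(fe$scaled)) < 1e-10))
  expect_true(all(abs(apply(fe$scaled, 1, sd) - 1) < 1e-10))
  # manual Dunn z for one pair (no ties in continuous data)
  vals <- abs(as.vector(fe$scaled))
  grp <- rep(names(do_founders), each = 40)
  rk <- rank(vals); N <- length(vals)
  z_manual <- (mean(rk[grp == "A"]) - mean(rk[grp == "B"])) /
    sqrt(N * (N + 1) / 12 * (1 / 40 + 1 / 40))
  row <- fe$dunn[fe$dunn$founder1 == "A" & fe$dunn$founder2 == "B", ]
  expect_equal(row$z, z_manual, tolerance = 1e-10)
})

test_that("inflated wild-derived effects are flagged by Dunn, others are not", {
  set.seed(51)
  eff <- matrix(rnorm(120 * 8, 0, 0.5), 120, 8)
  eff[, 6:7] <- eff[, 6:7] * 3  # CAST and PWK
  fe <- founder_enrichment(eff)
  expect_lt(fe$kruskal$p.value, 0.05)
  beats <- sapply(names(do_founders), function(f) {
    rows <- fe$dunn[fe$dunn$founder1 == f | fe$dunn$founder2 == f, ]
    sum(rows$p_adj < 0.05 & ((rows$founder1 == f & rows$z > 0) |
                               (rows$founder2 == f & rows$z < 0)))
  })
  expect_true(all(beats[c("F", "G")] >= 6))
  expect_true(all(beats[c("A", "B", "C", "D", "E", "H")] < 6))
})

test_that("colocalization finds exactly the overlapping same-chromosome pairs", {
  eq <- data.frame(phenotype = c("g1", "g2", "g3"), chrom = c("1", "1", "2"),
                   peak_mb = c(17, 40, 17), ci_lo = c(15, 38, 15),
                   ci_hi = c(25, 42, 25), stringsAsFactors = FALSE)
  mi <- data.frame(phenotype = c("mir1", "mir2"), chrom = c("1", "1"),
                   peak_mb = c(12, 17), ci_lo = c(10, 16), ci_hi = c(20, 18),
                   stringsAsFactors = FALSE)
  cl <- colocalize(eq, mi)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$distance_mb[cl$mirqtl == "mir1" & cl$eqtl == "g1"], 5)
  expect_equal(cl$distance_mb[cl$mirqtl == "mir2" & cl$eqtl == "g1"], 0)
  expect_false(any(cl$eqtl == "g3"))  # different chromosome

  # oracle equivalence against a brute-force all-pairs check
  set.seed(52)
  eq2 <- data.frame(phenotype = paste0("g", 1:30),
                    chrom = sample(c("1", "2"), 30, TRUE),
                    peak_mb = runif(30, 0, 100), stringsAsFactors = FALSE)
  eq2$ci_lo <- eq2$peak_mb - runif(30, 1, 8)
  eq2$ci_hi <- eq2$peak_mb + runif(30, 1, 8)
  mi2 <- data.frame(phenotype = paste0("mir", 1:10),
                    chrom = sample(c("1", "2"), 10, TRUE),
                    peak_mb = runif(10, 0, 100), stringsAsFactors = FALSE)
  mi2$ci_lo <- mi2$peak_mb - runif(10, 1, 8)
  mi2$ci_hi <- mi2$peak_mb + runif(10, 1, 8)
  cl2 <- colocalize(eq2, mi2)
  brute <- 0
  for (i in 1:10) for (j in 1:30) {
    if (mi2$chrom[i] == eq2$chrom[j] && mi2$ci_lo[i] <= eq2$ci_hi[j] &&
        eq2$ci_lo[j] <= mi2$ci_hi[i]) brute <- brute + 1
  }
  expect_equal(nrow(cl2), brute)
})

test_that("Fisher sample odds ratio matches the closed form and printed tables", {
  ft <- fisher_association(matrix(c(706, 1199, 540225, 866105), 2, 2))
  expect_equal(ft$odds_ratio,
               (706 * 866105) / (540225 * 1199), tolerance = 1e-12)
  expect_equal(round(ft$odds_ratio, 2), 0.94)
  ft2 <- fisher_association(matrix(c(4045, 4612, 1410, 1303), 2, 2))
  expect_equal(round(ft2$odds_ratio, 2), 0.81)
  ft3 <- fisher_association(matrix(c(5, 5, 5, 5), 2, 2))
  expect_equal(ft3$odds_ratio, 1)
  expect_equal(ft3$p_value, 1)
  ftz <- fisher_association(matrix(c(3, 0, 2, 4), 2, 2))
  expect_true(ftz$infinite_or)
  expect_true(ftz$p_value >= 0 && ftz$p_value <= 1)
})

test_that("correlation structure: monotone pairs, BH oracle, FDR control", {
  set.seed(53)
  n <- 60
  mirna <- matrix(rnorm(5 * n), 5, n,
                  dimnames = list(paste0("mir", 1:5), paste0("i", 1:n)))
  mrna <- matrix(rnorm(8 * n), 8, n,
                 dimnames = list(paste0("g", 1:8), paste0("i", 1:n)))
  mrna[1, ] <- exp(mirna[1, ])  # strictly increasing function
  cat <- setNames(rep("no-eQTL", 8), rownames(mrna))
  cat["g1"] <- "cis"
  cs <- correlation_structure(mirna, mrna, cat)
  r11 <- cs$records[cs$records$mirna == "mir1" & cs$records$mrna == "g1", ]
  expect_equal(r11$rho, 1.0)
  expect_true(all(cs$records$p_adj >= cs$records$p - 1e-15))

  # BH significance equals an independent step-up oracle on the same p's
  p <- cs$records$p
  m <- length(p)
  srt <- sort(p)
  k <- max(c(0, which(srt <= 0.05 * seq_len(m) / m)))
  expect_equal(sum(cs$records$significant), sum(p <= (if (k == 0) -1 else srt[k])))

  # independent noise panels: few BH-significant pairs
  mirna0 <- matrix(rnorm(20 * 100), 20, 100,
                   dimnames = list(paste0("a", 1:20), paste0("i", 1:100)))
  mrna0 <- matrix(rnorm(20 * 100), 20, 100,
                  dimnames = list(paste0("b", 1:20), paste0("i", 1:100)))
  cs0 <- correlation_structure(mirna0, mrna0,
                               setNames(rep("no-eQTL", 20), paste0("b", 1:20)))
  expect_lte(cs0$n_significant / cs0$n_pairs, 0.05)
  expect_error(correlation_structure(mirna0[, 1:2], mrna0[, 1:2],
                                     character(0)), "shared individuals")
})

test_that("differential expression filters at the boundary and recovers planted shifts", {
  n <- 200
  diet <- factor(rep(c("HP", "HFCA"), each = n / 2), levels = c("HP", "HFCA"))
  # feature exactly at the floor in exactly 25% of samples passes
  x <- c(rep(4, 50), rep(3, 150))
  panel <- rbind(at_floor = x, below = rep(3.9, n))
  colnames(panel) <- paste0("i", 1:n)
  expect_equal(unname(expression_filter(panel, 4, 0.25)), c(TRUE, FALSE))

  set.seed(54)
  base <- matrix(rnorm(50 * n, 7, 1), 50, n,
                 dimnames = list(paste0("f", 1:50), paste0("i", 1:n)))
  shifted <- 1:15
  base[shifted, diet == "HFCA"] <- base[shifted, diet == "HFCA"] + 2
  de <- differential_expression(base, diet, floor = 4, prevalence = 0.25)
  expect_gte(mean(de$significant[shifted]), 0.9)
  expect_true(all(de$direction[shifted] == 1))

  # permuted labels: essentially nothing significant
  de0 <- differential_expression(base[16:50, ], sample(diet), floor = 4,
                                 prevalence = 0.25)
  expect_lte(mean(de0$significant), 0.05)
  expect_error(differential_expression(base, factor(rep("a", n))), "two diet")
})

test_that("divergence scores follow the percent-difference definition and scale invariance", {
  b <- c(1, -0.5, 0.3, 0.8, -1.2, 0.6, -0.4, 0.2)
  expect_equal(divergence_score(b, b)$score, 0)
  # +1 -> +2 on one founder with others identical contributes 100
  b2 <- b; b2[5] <- 1.0
  b2h <- b2; b2h[5] <- 2.0
  dv <- divergence_score(b2h, b2)
  expect_equal(dv$percent_diff[5], 100)
  expect_equal(dv$score, 100)
  # invariance under a common positive rescaling
  set.seed(55)
  bh <- rnorm(8); bp <- rnorm(8)
  expect_equal(divergence_score(3.7 * bh, 3.7 * bp)$score,
               divergence_score(bh, bp)$score, tolerance = 1e-10)
})

test_that("allele-diet ranking combines ANOVA, concordance and divergence", {
  probs <- random_probs(200, 10, seed = 56)
  set.seed(57)
  diet <- factor(rep(c("HP", "HFCA"), 100), levels = c("HP", "HFCA"))
  dind <- as.numeric(diet == "HFCA")
  Z <- probs[, 4, ]
  # strong NZO-only-in-HFCA interaction + a no-interaction control
  y_int <- as.vector(Z %*% c(0, 0, 0, 0, 2.5, 0, 0, 0)) * dind +
    as.vector(Z %*% rnorm(8, 0, 0.3)) + rnorm(200, 0, 0.3)
  y_null <- as.vector(Z %*% rnorm(8, 0, 0.6)) + rnorm(200, 0, 0.3)
  pheno <- cbind(gi = y_int, gn = y_null)
  eff_cols <- paste0("eff_", names(do_founders))
  mk_peaks <- function(phens, effs) {
    pk <- data.frame(phenotype = phens, class = "mrna", model = "x",
                     chrom = "1", marker = "m004", peak_mb = 10, lod = 10,
                     threshold = 5, ci_lo = 8, ci_hi = 12, cis_trans = "cis",
                     var_explained = 0.3, h2 = 0.3, stringsAsFactors = FALSE)
    pk[eff_cols] <- effs
    pk
  }
  int_peaks <- mk_peaks(c("gi", "gn"), rbind(rnorm(8), rnorm(8)))
  hfca <- mk_peaks(c("gi", "gn"), rbind(c(0, 0, 0, 0, 1, 0, 0, 0) + 0.2,
                                        rep(0.5, 8)))
  hp <- mk_peaks(c("gi", "gn"), rbind(rep(0.2, 8), rep(0.5, 8)))
  rk <- allele_diet_ranking(int_peaks, hfca, hp, pheno, probs, diet)
  expect_true(all(rk$p_adj >= rk$p_interaction - 1e-15))
  gi <- rk[rk$phenotype == "gi", ]
  expect_true(gi$significant)
  expect_true(gi$concordant)
  expect_gt(gi$divergence_score, 0)
  expect_equal(rk$phenotype[1], "gi")
})
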