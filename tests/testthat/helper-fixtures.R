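# Shared fixture builders; all data generated in code, seeded.

# Small two-chromosome config for fast unit tests.
tiny_config <- function(n = 80, n_mrna = 10, n_mirna = 3, markers = 20L,
                        seed = 1, recomb_rate = 0.05) {
  sim_config(
    n_individuals = n,
    chromosomes = data.frame(chrom = c("1", "2"), length_mb = c(100, 100),
                             n_markers = c(markers, markers),
                             stringsAsFactors = FALSE),
    recomb_rate = recomb_rate, n_mrna = n_mrna, n_mirna = n_mirna,
    seed = seed
  )
}

# Hand-built allele-probability tensor from explicit homolog assignments.
# h1, h2: individuals x markers integer matrices of founder indices.
probs_from_homologs <- function(h1, h2, chrom = rep("1", ncol(h1)),
                                pos_mb = seq_len(ncol(h1))) {
  n <- nrow(h1); M <- ncol(h1)
  ids <- sprintf("i%02d", seq_len(n))
  mks <- sprintf("m%03d", seq_len(M))
  probs <- array(0, c(n, M, 8), dimnames = list(ids, mks, names(do_founders)))
  for (f in 1:8) probs[, , f] <- ((h1 == f) + (h2 == f)) / 2
  attr(probs, "map") <- data.frame(marker = mks, chrom = as.character(chrom),
                                   pos_mb = pos_mb, stringsAsFactors = FALSE)
  probs
}

# Random softened tensor for algebraic oracles.
random_probs <- function(n, M, seed = 1, chroms = 2) {
  set.seed(seed)
  h1 <- matrix(sample.int(8, n * M, replace = TRUE), n, M)
  h2 <- matrix(sample.int(8, n * M, replace = TRUE), n, M)
  chrom <- rep(as.character(seq_len(chroms)), each = ceiling(M / chroms))[1:M]
  pos <- stats::ave(seq_len(M), chrom, FUN = seq_along) * 2.5
  probs <- probs_from_homologs(h1, h2, chrom, pos)
  probs <- probs * 0.9 + 0.1 / 8  # soften so all founders have mass
  attr(probs, "map") <- data.frame(marker = dimnames(probs)[[2]],
                                   chrom = chrom, pos_mb = pos,
                                   stringsAsFactors = FALSE)
  probs
}

# Ground truth with a single planted QTL for one phenotype.
single_qtl_truth <- function(phenotype, marker, effects, tss_chrom, tss_mb,
                             h2 = 0, diet_effect = 0, background_sd = 1,
                             class = "cis", int_effects = NULL,
                             feature_class = "mrna") {
  qtl <- data.frame(phenotype = phenotype, marker = marker, class = class,
                    stringsAsFactors = FALSE)
  qtl[paste0("eff_", names(do_founders))] <- as.list(effects)
  if (!is.null(int_effects))
    qtl[paste0("int_", names(do_founders))] <- as.list(int_effects)
  ph <- data.frame(phenotype = phenotype, class = feature_class,
                   chrom = tss_chrom, tss_mb = tss_mb, h2 = h2,
                   diet_effect = diet_effect, background_sd = background_sd,
                   stringsAsFactors = FALSE)
  ground_truth(qtl, ph)
}
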