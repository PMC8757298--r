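Package: moqtl
Title: Multiparent Mixed-Model eQTL and mirQTL Mapping with Diet Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear mixed-model genome scans for expression QTL in
    multiparent outbred populations such as Diversity Outbred mice.
    Maps mRNA eQTL and miRNA mirQTL against eight-founder allele
    probabilities with leave-one-chromosome-out kinship, derives
    per-phenotype significance thresholds by permutation (including a
    two-stage 50-permutation screen), classifies peaks as cis or trans,
    characterizes them by BLUP founder allele effects, variance
    explained and narrow-sense heritability, and provides downstream
    architecture statistics: founder-allele enrichment, eQTL-mirQTL
    colocalization, miRNA-mRNA correlation structure, differential
    expression by diet, and ranking of allele-by-diet interactions.
    Includes a seeded generator of synthetic DO-style founder mosaics
    and expression panels with planted ground truth for end-to-end
    testing without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
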