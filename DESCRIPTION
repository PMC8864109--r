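Package: cernet
Title: Competing Endogenous RNA Network Inference from Multi-Omic Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Moderated differential expression with the random variance model
    (RVM) t-test, species-specific fold-change filtering, hierarchical
    clustering, over-representation analysis with two-sided Fisher and
    chi-squared tests under Benjamini-Hochberg control, Pearson co-expression
    networks with degree-based hub ranking, regulator-to-pathway projection
    networks, and lncRNA-miRNA-mRNA competing-endogenous-RNA (ceRNA) triplet
    inference. Includes a calibrated multi-omic expression simulator that
    plants differential features, co-expression hubs and sponge triplets with
    known ground truth, so every stage of the inference chain can be validated
    by recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
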