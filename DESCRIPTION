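Package: dnalmprobe
Title: Probing What DNA Language Models Learn
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for probing whether masked DNA language models built on
    overlapping k-mer tokenization learn sequence context or merely token
    identity. Provides overlapping k-mer vocabularies and tokenization,
    construction of masked-token prediction samples with per-k mask patterns,
    the next-k-mer fine-tuning benchmark, and the Prom300 task (intact
    promoters versus composition-preserving part-shuffled negatives), together
    with a small trainable transformer reference model, a Word2Vec CBOW
    baseline, embedding analyses (maximum explainable variance, UMAP with
    purine/pyrimidine annotation), evaluation metrics including the Matthews
    correlation coefficient, and synthetic-genome generators with known
    statistical structure for positive and negative controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    uwot
Suggests:
    cluster,
    GenomicRanges,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
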