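Package: topicensemble
Title: Consensus Clustering of Transcripts with NMF Topic Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised two-group screening of interview transcripts.
    Documents are represented by TF-IDF weights with rule-based pruning of
    common and rare words, decomposed by an ensemble of non-negative matrix
    factorization runs under different random seeds, and consolidated by
    complete-linkage hierarchical clustering of the pooled topics into two
    consensus groups. Includes evaluation against external binary labels
    (confusion matrix, accuracy, class-wise rates), mutual-information
    feature ranking with a word-fraction experiment, classical
    multidimensional-scaling diagnostics, and a synthetic labelled corpus
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices, jsonlite, stringi
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
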