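Package: stressmem
Title: Dehydration Stress Memory Analysis of Transcriptome and Physiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing stress-memory responses of plants exposed to
    repeated dehydration stress. Classifies per-gene transcriptional responses
    across watered, first-stress and repeated-stress stages into memory,
    delayed-memory, non-memory and non-responsive sign patterns; detects
    co-expressed gene modules by average-linkage clustering of a correlation
    dissimilarity with a deterministic dynamic tree cut; summarises modules by
    eigengenes (first principal components) and groups them into meta-modules;
    tests Gene Ontology term over-representation per module with
    Benjamini-Hochberg false discovery rate control; derives chlorophyll
    fluorescence and gas-exchange parameters from raw readings and classifies
    their memory patterns; and correlates module eigengenes with physiological
    parameters. A synthetic-data generator with planted ground truth supports
    end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
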