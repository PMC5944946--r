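Package: ribophase
Title: Paired rDNA/rRNA Metabarcoding Analysis of Seasonal Plankton Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing paired 18S rDNA/rRNA amplicon surveys of
    planktonic microbial eukaryotes. Reads OTU count tables (TSV and mothur
    'shared' dialects), filters and rarefies them, computes alpha-diversity
    indices (Chao-1, Simpson, Shannon equitability) with a permutation-based
    index comparison, clusters samples on Bray-Curtis dissimilarity with a
    SIMPROF similarity-profile permutation test, ordinates environmental
    variables (Box-Cox, PCA, Ward grouping), and implements the signed
    rRNA:rDNA relative-activity framework: reduced-major-axis regression of
    log rRNA on log rDNA relative abundance per taxonomic group, four-quadrant
    abundance/activity life-cycle phase classification, and bloom
    early-warning detection. Includes a synthetic seasonal community
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
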