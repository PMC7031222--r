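Package: rpconnect
Title: Connectivity Mapping with Exact Rank-Product Statistics for Drug
    Repositioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Matches time-course differential-expression signatures against
    ranked drug-perturbation profiles (Connectivity-Map style) using
    rank-product statistics with exact tail probabilities under the
    with-replacement null, and integrates the evidence across a panel of
    signatures into statistically ranked lists of positively and negatively
    connected compounds.  Includes signature extraction from
    differential-expression tables, cross-species ortholog translation,
    readers and writers for GMT/GCT/TSV, a synthetic-data generator with
    planted connectivity for end-to-end validation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
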