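Package: tbitriage
Title: Multi-Criteria Triage of Repurposing Candidates for Traumatic Brain Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for triaging drug-repurposing candidates
    discovered by transcriptomic connectivity mapping in a traumatic brain
    injury (TBI) model. Builds acute and chronic differential-expression
    signatures from fold-change/FDR tables, converts compound-signature
    concordance scores into percentile-band points, analyses neuron-microglia
    co-culture plate assays (percent-of-control, exact Mann-Whitney tests,
    dose dependence), quantifies qPCR target engagement with the delta-Ct
    method and batch-adjusted regression, combines all evidence into a
    weighted go/no-go composite score, and evaluates longitudinal plasma
    cytokine panels with nested cross-validated gradient-boosted trees and
    permutation testing. A seeded synthetic-data generator emulates every
    wet-lab input so the full pipeline runs and is tested without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    ranger
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
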