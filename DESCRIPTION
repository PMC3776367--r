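Package: adrnet
Title: Network-Based Ranking of Drug Side Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts and ranks adverse drug reactions (side effects) for a
    query compound by guilt-by-association over chemical-chemical and
    protein-chemical interaction networks in the STITCH dialect. Direct
    interaction evidence is summed over labelled training drugs; when a query
    has no interactive training partner, a hybrid score built from shared
    chemical and protein neighbours takes over. A Tanimoto structural
    similarity baseline, a benchmark builder for SIDER-style label tables
    (top-k side effects, interaction-coverage filter, virtual-drug
    accounting, random train/test split), order-wise jackknife and hold-out
    accuracy profiles, and a synthetic community-network fixture generator
    are included, along with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
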