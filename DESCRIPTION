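Package: chemotrace
Title: Phylogenetic Chemosystematics of Scent-Gland Quinones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing the evolutionary history of glandular secretion
    chemistry on phylogenies. Compiles compound-detection tables (GC-MS
    presence/absence screens) into binary phylogenetic characters, reconstructs
    ancestral states under asymmetric-cost (Sankoff) parsimony with full
    enumeration of most-parsimonious reconstructions and gain/loss event
    counting, and ranks competing origin hypotheses as edge-constrained
    reconstructions. Includes Kovats retention-index computation and
    library-based peak annotation for GC-MS identification, a continuous-time
    Markov simulator of binary traits on trees for method validation, and a
    packaged case study on quinones in harvestman (Opiliones) scent glands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
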