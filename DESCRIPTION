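Package: remhom
Title: Family-Based Remote Protein Homology Detection via Relational
    Pattern Mining and Propositional Classifiers
Version: 0.1.0
Authors@R:
    person("remhom", "developers", email = "remhom@example.org",
           role = c("aut", "cre"))
Description: Detects remote protein homologs at the superfamily level by
    encoding sequences and multiple sequence alignments as first-order
    logic ground atoms (physico-chemical composition predicates,
    alignment-column predicates and derived conserved physico-chemical
    column predicates), mining frequent conjunctive patterns from the
    positive training family with a level-wise APRIORI-style miner,
    propositionalizing the mined rules into binary features, and training
    RBF-kernel support vector machines or decision trees.  Includes a
    profile hidden Markov model with Viterbi decoding to project query
    residues onto training-alignment columns, a leave-one-family-out
    evaluation protocol with balanced negative resampling and averaged
    AUC-ROC, and a synthetic superfamily benchmark generator with planted
    conserved columns and identity calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Matrix,
    quadprog,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
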