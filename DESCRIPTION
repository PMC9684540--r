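Package: foldsmith
Title: Dynamic De Novo Protein Backbone Design with Ranged Fold Definitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A backbone design engine for small de novo proteins. Folds are
    declared as ranged definitions (secondary-structure elements with length
    ranges, loop ABEGO menus, strand pairings with register shifts and bulges,
    and ambiguous distance constraints) rather than fixed per-residue
    blueprints. A divide-and-conquer planner splits each fold into minimal
    pairing-complete subsegments that are folded incrementally by Metropolis
    Monte-Carlo fragment insertion, with a perturber that permutes subsegment
    parameters whenever geometric filters reject a build. Downstream utilities
    compute shape-diversity descriptors (inter-element distances, helix and
    sheet dihedrals, opening angles), protease-stability success rates, and a
    Gini random-forest stability classifier with out-of-bag and
    leave-one-fold-out evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    yaml,
    xml2,
    jsonlite,
    randomForest,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
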