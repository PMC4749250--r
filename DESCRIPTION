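Package: admixsel
Title: Local-Ancestry Scans for Recent Selection in Admixed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to detect and quantify recent positive selection in
    three-way admixed cohorts from local ancestry.  Implements a two-layer
    haplotype-cluster hidden Markov model fitted by a weighted EM algorithm,
    in which training (reference-panel) and cohort samples receive different
    weights so that one ancestral training panel may be absent and its
    haplotypes learned from the cohort itself.  Includes a forward-time
    admixture simulator with recombination hotspots, haploid viability
    selection and phasing switch-error injection; family-aware genome scans
    of average ancestry dosages standardized by their sample standard
    deviation; and selection-coefficient estimation from pre- and
    post-selection dosages under simple, dominance and additive models by
    closed form or interval bisection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
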