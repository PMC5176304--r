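Package: uoxkit
Title: Computational Engineering Toolkit for a Therapeutic Uricase
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable, tested implementations of the computational steps used
    to engineer a PEGylated therapeutic urate oxidase (uricase): structure-based
    selection of cysteine substitution sites on a homotetramer from
    solvent-accessible surface area (Shrake-Rupley, implemented here) and
    active-site distance criteria; sequence-engineering utilities (pairwise
    identity, alignment consensus, motif substitution, C-terminal truncation,
    mass and extinction-coefficient calculators); Michaelis-Menten kinetics
    from substrate-depletion progress curves; mono-exponential pharmacokinetic
    fitting (IV and subcutaneous terminal phase); and stimulation-index
    statistics for T-cell proliferation assays. A synthetic-data module
    generates ground-truthed inputs for every stage so the whole workflow runs
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
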