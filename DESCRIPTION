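Package: cycloMS
Title: Mass-Spectrometric Discovery Workflow for Cyclic Cystine-Knot Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the mass-spectrometric characterization of head-to-tail
    cyclic, cystine-knotted peptides (cyclotides): monoisotopic and average mass
    arithmetic for linear and cyclic species with disulfides and chemical
    modifications, in-silico proteolysis of cyclic backbones with missed
    cleavages, b/y fragment-ion series generation and MS/MS spectrum annotation,
    inference of cysteine count and backbone cyclicity from reduction/alkylation
    and ring-opening mass shifts, six-frame translation and cyclotide precursor
    mining from transcript contigs, intercysteine-loop decomposition and
    sequence comparison, dose-response (constrained four-parameter logistic)
    and one-phase decay fitting for protease-inhibition assays, and seeded
    synthetic-data generators with known ground truth for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
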