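Package: dityrims
Title: Ion Mobility Mass Spectrometry Analysis of Di-Tyrosine
    Cross-Linked Peptide Oligomers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising covalently cross-linked peptide
    oligomers by travelling-wave ion mobility mass spectrometry (IMS-MS).
    Computes elemental compositions, isotopic distributions and average or
    monoisotopic masses of peptide oligomers carrying tyrosine-tyrosine
    cross-links (2 Da loss per bond); simulates seeded two-dimensional
    (m/z by drift time) spectra of oligomer mixtures; assigns charge state
    and oligomer order from isotopic-envelope peak spacing; infers
    cross-link stoichiometry from before/after mass shifts; calibrates the
    drift-time to collisional-cross-section power law against standards of
    known cross-section; and quantifies compact-versus-extended conformer
    population shifts by shared-center Gaussian decomposition of drift-time
    profiles. Ships the human amyloid-beta 1-40 peptide as the default
    sequence and a transcribed oligomer reference table for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    seqinr,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
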