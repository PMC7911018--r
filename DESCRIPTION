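Package: vhhumanize
Title: Nanobody Humanization by CDR Grafting with Aggregation-Risk Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for humanizing camelid single-domain antibodies (VHH,
    nanobodies) by grafting complementarity-determining regions onto a
    human-hallmark acceptor scaffold, and for predicting the structural
    consequences. Provides scheme numbering and framework/CDR annotation
    of VHH sequences, detection of the framework-2 hallmark tetrad
    (camelid FERF versus human VGLW), construction of chimeric and
    mutant panels with numbering-aligned difference accounting and
    species-fingerprint classification, per-residue solubility profiling
    with structural correction and aggregation-hotspot scoring,
    solvent-accessibility and residue contact-map difference analysis,
    gromos RMSD clustering of conformational ensembles, and a synthetic
    sequence/structure generator with planted ground truth for
    closed-loop testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
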