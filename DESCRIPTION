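Package: ProteoSplice
Title: Identification and Quantification of Proteasome-Generated Spliced
    Peptides from In Vitro Digestions
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mass-spectrometry-based identification and
    quantification of proteasome-catalysed peptide splicing (PCPS) products
    in in vitro digestions of synthetic polypeptide substrates. Enumerates
    all theoretically possible non-spliced and cis-spliced peptide products
    of a substrate with full coordinate bookkeeping, computes monoisotopic
    masses and theoretical b-, a- and y-fragment ions with neutral losses
    and variable modifications, annotates MS2 peak lists, discriminates
    isobaric spliced/non-spliced candidates through diagnostic fragment
    ions and retention-time matching, applies ion-score/q-value/delta-score
    identification filters, and quantifies digestion kinetics by extracted
    ion chromatogram (XIC) peak detection and integration. Seeded
    simulators of digestion time courses, MS2 spectra, chromatogram runs
    and search-hit tables allow every pipeline stage to be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
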