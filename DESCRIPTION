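Package: coixpep
Title: In Silico Gastrointestinal Proteolysis and Quality Indices for Coix Seed Prolamin Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for assessing a cereal storage protein as a precursor of
    bioactive (notably DPP-IV-inhibitory) peptides. Simulates gastric and
    intestinal proteolysis with explicit, overridable cleavage-rule tables and
    reports the degree of hydrolysis and a peptide length census; computes
    peptide monoisotopic and average masses and structure-activity motif flags;
    ingests external predictor score tables and applies threshold-based
    screening; derives amino-acid-based nutritional and flavour quality indices
    (amino acid score, protein efficiency ratio regressions, class sums, taste
    activity values); provides calculators for plate-based enzyme-inhibition,
    biuret peptide quantitation, ANS surface hydrophobicity and extraction-rate
    arithmetic; and estimates protein secondary-structure fractions from amide I
    band Gaussian deconvolution of FTIR or Raman spectra, with Raman tyrosine
    doublet and disulfide conformer classifiers. Seeded synthetic-data
    generators with independent ground truth make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
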