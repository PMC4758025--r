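Package: xlinkr
Title: Isotope-Coded Cross-Linking Mass Spectrometry with Structural
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identification and validation of chemically cross-linked
    peptides from tandem mass spectra using isotope-coded (light/heavy)
    amine-reactive linkers such as BS3-H12/D12. Implements in-silico
    tryptic digestion, cross-link candidate enumeration with decoy-based
    false discovery rate control, pairing of light and heavy assignments
    under three validation criteria (dual identification, co-elution,
    fragment-pattern similarity), solvent-accessible surface distance
    filtering against crystal structures, CAPRI-style assessment of
    docking models, and steady-state surface plasmon resonance affinity
    fitting. A synthetic-data generator produces toy complexes, planted
    cross-links and paired spectra so the whole workflow is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    bio3d,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
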