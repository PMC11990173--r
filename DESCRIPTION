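Package: glycoladder
Title: Oligosaccharide Annotation from Negative-Mode LC-MS/MS via
    Neutral-Loss Fragment Ladders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates hexose/pentose oligosaccharides in centroided
    negative-mode LC-MS/MS data. Enumerates residue compositions
    consistent with each deprotonated precursor mass under a
    monosaccharide palette constraint, verifies candidates against
    predicted Y-ion neutral-loss fragment ladders (sequential losses of
    162.0528 Da hexose and 132.0423 Da pentose residues with water-loss
    companions), classifies hits into fructo-oligosaccharide,
    arabino-oligosaccharide and mixed series, assembles co-eluting
    isomer groups, and reports Metabolomics Standards Initiative
    confidence levels. Includes a parallel-reaction-monitoring
    inclusion-list generator, mzML/MGF/CSV input and output, a synthetic
    spectra simulator with ground truth for benchmarking, and a curated
    44-compound plant oligosaccharide benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
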