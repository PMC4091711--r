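Package: choreoscope
Title: Single-Cell Choreography of Bacterial Chromosome Segregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the segregation choreography of bacterial
    chromosomes from snapshot fluorescence-microscopy focus tables.
    Cells are classified by length into 0.1 um intervals and locus
    statistics (duplication frequency, position percentiles, inter-locus
    and sister-locus distances, per-pole polarity) are computed with a
    0.3 um sliding window. Includes new-pole/old-pole axis orientation
    inference, cross-strain cell-length realignment, and a steady-state
    cell-population simulator for the two Vibrio cholerae chromosomes
    with perturbation scenarios (displaced or deleted parS sites,
    ectopic replication origin) that provides ground truth for testing
    the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
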