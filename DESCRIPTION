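Package: fragtree
Title: Fragmentation Trees from Multistage Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds elemental-formula-annotated fragmentation trees from
    multistage (MSn) mass spectra. Candidate CHNOPS formulas are assigned to
    fragment ions under precursor-product constraints (a fragment cannot
    contain more atoms of an element than its precursor, and fragment plus
    neutral loss must add up to the precursor), with ppm mass tolerance,
    element-ratio plausibility rules and a non-integer RDBE filter. Peaks
    that admit no formula consistent with the spectral hierarchy are removed
    as artifacts. Trees are represented as collections of elemental formula
    paths (EFPs), aggregated into consensus trees over repeated acquisitions,
    and compared between compounds via the Tanimoto coefficient, hierarchical
    clustering and composite-spectrum dot products. A data-dependent
    acquisition simulator generates synthetic MSn runs (mzXML or an internal
    JSON peak-tree format) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    xml2,
    mzR,
    ape,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
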