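Package: zoomsid
Title: Collagen Peptide Mass Fingerprinting (ZooMS) Identification and
    Assemblage Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for taxonomic identification of archaeological bone by
    Zooarchaeology by Mass Spectrometry (ZooMS). Reads MALDI-TOF collagen
    mass fingerprints (mzML or plain text), applies segment-minimum baseline
    correction, Savitzky-Golay smoothing and signal-to-noise thresholded
    peak picking, matches picked peaks against a taxon x peptide-marker
    reference library, resolves the smallest taxonomic category consistent
    with the observed markers, and aggregates per-sample identifications
    into ZNISP assemblage tables, morphological-NISP comparisons and spatial
    collagen-preservation grids. A synthetic-fingerprint simulator with
    per-marker dropout, lognormal intensities, baseline drift and replicate
    spotting supports end-to-end validation without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
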