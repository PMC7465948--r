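Package: gcdeconv
Title: GC/MS Chromatogram Deconvolution with PARAFAC2 and Pseudo-Replicate Augmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resolves co-eluting GC/MS peaks from a single chromatogram by
    deriving a five-member pseudo-replicate set (intensity scaling plus
    sub-scan retention-time shifting), fitting non-negativity-constrained
    PARAFAC2 models to user-defined retention intervals, diagnosing model
    adequacy with fit percentage and core consistency (CORCONDIA), and
    identifying the resolved component spectra against MSP spectral
    libraries with forward and reverse match factors. Includes a synthetic
    chromatogram simulator with known ground truth, ANDI/AIA netCDF
    readers and writers, and per-compound AMF/ARMF report aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ncdf4,
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
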