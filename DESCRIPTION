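Package: fetterp
Title: Full-Evaporation Headspace GC-MS Terpene Profiling of Cannabis Flowers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative terpene profiling of cannabis flower
    material by headspace full evaporation technique (FET) GC-MS. Ships a
    45-terpene analyte panel with an n-alkane retention-index ladder used as
    internal standard, experimental verification of full evaporation
    (thermostatting scans, sample-size linearity, multiple headspace
    extraction depletion fits), retention-index and qualifier-ion
    identification, unweighted linear calibration with Cochran
    variance-homogeneity and Mandel linearity testing and automatic
    split/restricted range selection, DIN 32645 analytical limits and
    GTFCh-style bias and precision statistics, ISTD-normalised
    quantification with re-weigh verification, and per-strain profile
    summaries. A synthetic peak-table generator emulating FET physics
    (evaporation kinetics, thermal degradation, matrix suppression,
    geometric headspace depletion, detector saturation) makes the whole
    pipeline testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
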