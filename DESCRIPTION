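Package: nasalGC
Title: Reduced-Order Models of Nasal Airflow, Odorant Uptake and
    Chromatographic Efficiency
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying the mammalian nose as a coiled parallel gas
    chromatograph. Generates synthetic nasal channel networks (parallel
    ethmoid coils fed by a high-speed dorsal medial stream, and straight-tube
    analogues), solves pressure-driven laminar flow on the channel network,
    computes odorant uptake through an air/mucus partition wall condition
    (with a two-dimensional Graetz-type reference solver as numerical oracle),
    and evaluates gas-chromatographic efficiency of the olfactory channels via
    the Golay plate-height equation and theoretical plate numbers, including
    cross-species comparisons under documented calibrations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    Matrix,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
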