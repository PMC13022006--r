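Package: sestonmix
Title: Trophic Mode Detection in Marine Seston from Amino Acid Nitrogen Isotopes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting mixotrophy and mixoplankton activity in
    marine seston from compound-specific nitrogen isotope analysis of amino
    acids (CSIA-AA). Computes trophic positions from the glutamic acid-,
    alanine- and phenylalanine delta15N pairs, draws trophoclines, classifies
    samples into four nutritional modes (photoautotrophy with osmotrophy
    and/or phagotrophy added to it), unmixes diagnostic pigment
    concentrations into microalgae class contributions by a ChemTax-style
    ratio-matrix factorization, derives station-level hydrographic predictors
    (mixed-layer depth, buoyancy frequency, nutriclines, nitrate availability
    index, oxygen saturation, plume thickness), clusters pigment communities,
    and induces a gain-ratio decision tree predicting the dominant trophic
    mode. Includes a synthetic-data generator with known ground truth
    emulating a river-plume study design, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
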