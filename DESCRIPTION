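Package: paleorain
Title: Nearest-Living-Relative Bioclimatic Reconstruction of
    Paleo-Precipitation and Model-Data Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs precipitation at fossil plant localities with the
    nearest-living-relative (NLR) bioclimatic analysis: six precipitation
    bioclim variables (MAP, WMP, DMP, PS, WQP, CQP) are derived from monthly
    climatologies, per-taxon Gaussian climatic envelopes are fitted from
    cleaned and spatially thinned occurrence records, and a maximum-likelihood
    climate combination with a relative-likelihood uncertainty range is found
    by a grid search over sampled extant climates. A companion gridded-field
    toolkit supplies multi-model ensemble means, bilinear regridding, seasonal
    and regional averages, zonal means and RMSE, plus Euler-pole rotation of
    site coordinates and model-versus-reconstruction comparison tables. A
    seeded synthetic-data generator produces climatology grids, occurrence
    sets with known envelopes and pseudo-model ensembles so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
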