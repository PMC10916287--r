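Package: dropxtal
Title: Droplet-Microfluidic Crystallization Statistics, Synthetic Microscopy
    and In-Droplet Micromixing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for droplet-microfluidic preparation of protein
    microcrystals for serial crystallography. Implements Poisson encapsulation
    statistics (occupancy, single-crystal fraction, lambda estimation with exact
    Poisson-mean confidence intervals), sphere-equivalent droplet geometry and
    generation-frequency bookkeeping, mass-balance prediction of crystal size from
    droplet volume and crystallization recipe, into-crystal substrate diffusion
    times, a synthetic-microscopy generator for droplet fields and mixing image
    sequences with ground truth, image-based droplet and crystal measurement, a
    finite-volume advection-diffusion simulator of convective-diffusive mixing
    inside transported droplets with the pixel-intensity coefficient-of-variation
    mixing-time statistic, and serial-crystallography hit/indexing-rate accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
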