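Package: rumenbalance
Title: Nutritional Geometry of Rumen Macronutrient Balance in Wild Browsers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for proportions-based nutritional geometry of ruminant
    forage and rumen composition. Derives macronutrient profiles (available
    protein, cellulose, hemicellulose, nonstructural carbohydrates plus
    lipids, microbial nitrogen) from proximate wet-chemistry measurements
    with compositional closure guarantees, projects three-component mixtures
    into right-angle mixture triangle coordinates, delimits convex
    nutritional spaces, and runs the accompanying statistics: standardized
    isometric-scaling regression, protein-to-carbohydrate ratio models with
    diet-type interactions, Pearson correlation matrices, one-way ANOVA with
    Tukey comparisons, and principal component analysis of the foodscape.
    Includes a seeded synthetic-data generator emulating the correlation
    structure of winter moose rumen samples and a simplified latent-variable
    calibration stage for near-infrared reflectance spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
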