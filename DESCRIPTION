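Package: sorghumTPE
Title: Drought-Scenario Characterization of Sorghum Production Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A daily-timestep simulator for photoperiod-sensitive sorghum in the
    Sahelian and Sudanian zones of Mali, coupled to a stochastic monsoonal weather
    generator and a layered soil-water bucket. Phenology follows a thermal-time
    stage machine with a triple broken-linear photoperiod response; canopy size is
    built from a bell-shaped individual-leaf-area profile so that photoperiod-driven
    changes in leaf number propagate to leaf area, transpiration demand and the
    daily crop water supply/demand ratio. Seasonal supply/demand trajectories around
    flowering are clustered (k-means or PAM) into drought-stress scenarios, weighted
    by isohyet season availability, and summarized as scenario frequencies and
    yield distributions per isohyet, soil and cultivar. Includes goodness-of-fit
    statistics and divergence-line coverage for model evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, cluster, yaml, graphics
Suggests: testthat (>= 3.0.0), mclust, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
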