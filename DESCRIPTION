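Package: springrisk
Title: Spring-Water Hydrochemistry, Quality Indices and Health-Risk Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for seasonal spring-water chemistry analysis: ion
    equivalent conversions and charge-balance quality control,
    hydrochemical facies classification (Piper, Chadha and Gibbs
    coordinates, ionic ratios, chloro-alkaline indices), water-quality and
    contamination indices (CCME water quality index, heavy metal pollution
    index, heavy metal index, Hakanson potential ecological risk index),
    deterministic and Monte-Carlo USEPA-style health risk (chronic daily
    intake, hazard quotients and indices, carcinogenic risk), and
    corrosion/scaling potential indices (Langelier, Ryznar, Puckorius,
    Aggressive, Larson-Skold, Revelle, chloride-sulphate mass ratio). A
    seasonal synthetic-data generator emulates a six-spring monitoring
    campaign so every stage of the pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
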