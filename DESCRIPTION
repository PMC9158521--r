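Package: chillforce
Title: Chilling-Forcing Models of Spring Phenology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates species-specific relationships between winter chilling
    accumulation and the heat (forcing) requirement of spring phenological
    events from twig-cutting experiments, and uses them to simulate budburst
    and flowering dates over multi-decade climate series. Includes hourly
    temperature interpolation from daily extremes, threshold/range/triangular
    chilling-unit models, growing-degree-hour accumulation, bounded nonlinear
    least-squares fitting of the exponential chilling-forcing curve, chilling
    sensitivity and basic forcing requirement traits, annual onset simulation
    with decomposition of phenological change into chilling and forcing
    contributions, trend and trait-correlation statistics, and seeded
    synthetic generators for weather and twig experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    lme4,
    lmerTest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
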