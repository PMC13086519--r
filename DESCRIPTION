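Package: denitkin
Title: Denitrification Kinetics and Nitrite-Accumulation Phenotyping in
    Sealed Batch Vials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mechanistic simulation and analysis of denitrification kinetics
    in sealed, stirred batch incubations monitored by a robotized headspace
    autosampler. Provides a gas-liquid partitioning model of the vial, an
    electron-allocation ODE simulator of a denitrifying batch culture with
    phenotype-specific regulation (NO3--gated nitrite reduction, reductase
    synthesis delays, electron competition among terminal reductases), an
    instrument-style observation model with sampling dilution and measurement
    noise, sampling-loss-corrected nitrogen mass balance with spline
    interpolation of sparse NO2- measurements, electron-flow partitioning to
    the terminal reductases, classification of runs into full, partial and
    low nitrite-accumulation phenotypes, and one-way ANOVA with Tukey HSD
    compact letter displays for group comparisons of intermediate maxima.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    multcomp,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
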