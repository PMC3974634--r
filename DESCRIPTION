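Package: GeneTargeting
Title: Mechanistic Simulation and Marker-Retention Analysis of Human Gene Targeting
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and analysis of homologous-recombination
    mechanisms underlying gene targeting in human somatic cells. Simulates
    ends-out double-strand-break repair with uniformly distributed Holliday
    junction resolution, single-strand assimilation, DSB-induced ends-in
    recombination under drug selection, SDSA/dissolution alternatives, random
    integration, and mismatch-repair anti-recombination. Provides per-marker
    retention profiles with linear and exponential model fits, mitotic
    sectoring and trans/cis subclone configuration analysis, a double-event
    mixture estimator, per-clone pathway classification, and mismatch-repair
    efficiency calibration, all exercised on synthetic clone genotype tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
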