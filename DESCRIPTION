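Package: androscape
Title: Multi-Scale Model of Androgen-Regulated Prostate Epithelium
Version: 0.1.0
Authors@R:
    person("androscape", "maintainers", email = "androscape@example.org",
           role = c("aut", "cre"))
Description: Simulates androgen-regulated prostate epithelial dynamics on
    three coupled scales: intracellular chemical kinetics of testosterone
    influx, 5-alpha-reductase conversion to dihydrotestosterone (DHT), and
    mass-action binding of both androgens to the androgen receptor (AR)
    under homeostatic AR production; an androgen- and oxidative-stress
    driven tissue growth model with Hill-type proliferation and apoptosis
    signals; and a deterministic mutation-selection state-transition model
    of selection on homeostatic AR expression across competing epithelial
    strains. Includes steady-state calibration utilities (influx inference
    from finasteride-condition data, reductase-parameter fitting, unit
    conversions), a synthetic tissue-concentration dataset generator for
    parameter-recovery testing, scenario sweeps over serum testosterone and
    5-alpha-reductase inhibition, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
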