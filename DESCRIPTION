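Package: parayield
Title: Treatment Effects on Host Rearing and Egg-Parasitoid Yield
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical analysis of a host-rearing experiment in which a
    juvenile-hormone analog (pyriproxyfen) and photoperiod treatments drive
    survival, egg production and egg viability of the kudzu bug (Megacopta
    cribraria), and emergence of the egg parasitoid Paratelenomus saccharalis
    reared on those eggs.  Provides a calibrated synthetic-data generator for
    the two-collection factorial rearing design, censored Weibull accelerated
    failure-time models with hazard-ratio conversion, negative-binomial and
    hurdle count regression with estimated marginal means and Tukey-adjusted
    compact letter displays, clutch-weighted binomial logistic regression for
    eclosion and emergence rates, and Monte-Carlo propagation of fecundity and
    emergence uncertainty into parasitoid yield per treatment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    emmeans,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
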