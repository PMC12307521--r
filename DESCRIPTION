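Package: morphrep
Title: Component-Based Gestural Repertoires for Great Apes
Version: 0.1.0
Authors@R:
    person("Repertoire", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds great-ape gestural repertoires from coded gesture-token
    tables at two levels of granularity: gesture actions (coarse units,
    included when observed at least three times) and morphs (fine units,
    detected as latent classes of four categorical modifiers - body part,
    contact with recipient, lateral use, repetition - within each gesture
    action, via a multinomial latent-class mixture fitted by EM with BIC
    model selection). Also computes token-contribution tables, the
    repertoire of regular use, detection-asymptote (accumulation) curves,
    individual repertoire sizes and gesturing rates by maturation and sex
    class, behavioural-context distributions at the communication level,
    and inter-rater agreement (Cohen's kappa) on proportional subsamples.
    Includes a calibrated synthetic gesture-token generator with planted
    latent structure so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
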