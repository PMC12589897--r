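Package: limbflux
Title: Arteriovenous Forearm Balance, Tracer Kinetics and Clamp Analytics
    for Limb Immobilization Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis chain for limb-immobilization
    tracer-physiology studies: Doppler-derived brachial artery blood flow,
    arteriovenous forearm balance and two-pool stable-isotope dilution
    kinetics (net balance, rate of appearance and disappearance),
    hyperinsulinaemic-euglycaemic clamp glucose disposal rate, deuterated
    water fractional synthesis rates, accelerator mass spectrometry
    carbon-14 quantification, and small phenotyping reducers (grip strength,
    myofibre cross-sectional area distributions). Forward simulators (a
    steady-state virtual forearm, a closed-loop virtual clamp subject, and
    a calibrated synthetic mouse cohort) provide known ground truth so that
    every estimator can be validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
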