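Package: equifacs
Title: Analysis of Equine Facial Action Coding (EquiFACS) Event Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-coded facial action annotations of horses
    (EquiFACS) together with heart-rate recordings from putatively stressful
    management interventions such as road transportation and social isolation.
    Provides readers for annotation event tables, clip metadata and Polar HRM
    R-R interval files; construction of the "ear flicker" facial movement index
    from near-simultaneous ear action descriptors; frequency-threshold action
    unit selection (the HFI method); event-anchored directed co-occurrence
    graphs over observation windows with paired condition contrasts; per-clip
    frequency and maximum-duration summaries with paired nonparametric tests
    and the Wexler inter-rater agreement ratio; R-R artifact filtering and
    clip-anchored five-minute mean heart rate with Holm-corrected paired tests;
    leave-one-out linear support-vector-machine discrimination of intervention
    versus baseline clips; and a calibrated synthetic study generator so the
    whole pipeline is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    e1071,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
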