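Package: crewnet
Title: Wearable Proximity Networks and Longitudinal Psychometrics for
    Isolated, Confined and Extreme (ICE) Crews
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing team dynamics in isolated, confined and
    extreme environments from wearable proximity-sensor contact streams and
    repeated questionnaire batteries. Contact intervals recorded at 10-second
    resolution are aggregated into per-deployment weighted interaction
    networks, from which strength centrality, per-node Gini selectivity,
    daily-strength distributions and nationality-group contact matrices are
    computed. Questionnaire items are scored into loneliness, paranoid
    thinking, cohesion, conflict and performance scales; longitudinal change
    is estimated with complete-case repeated-measures ANOVA, paired t tests
    and two-level linear growth models with person-level bootstrap confidence
    intervals; sensor metrics are linked to psychological scores through
    person-mean-centred within-subject Spearman correlations. A synthetic
    crew simulator generates contact logs and questionnaire panels with known
    ground truth so that the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
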