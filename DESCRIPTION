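Package: vitaltrace
Title: Intravital Leukocyte Track Classification and Ratiometric Calcium
    Response Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for two live-imaging assays used in
    neuro-immunology studies of airway inflammation: (1) intravital
    microscopy cell tracks, with per-track motility metrics (duration,
    mean speed, net and total displacement) and a rule-based four-class
    leukocyte behavior classifier (adherent, crawling, patrolling,
    tethering) summarized per field of view; and (2) ratiometric
    (Fura-2 F340/F380) calcium imaging of sensory neurons, with 15-second
    maximum compression, stimulation-window response amplitudes against a
    pre-stimulus baseline, KCl-gated responder calling, per-dish averaging
    and batch-wise vehicle normalization. Includes seeded synthetic-data
    generators (correlated random-walk tracks with known behavior labels;
    calcium traces with known responder labels) so every stage can be
    validated against ground truth, plus nested replicate aggregation,
    classical group comparisons and a deterministic JSON run report.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
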