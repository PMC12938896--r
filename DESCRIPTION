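Package: ranobm
Title: Longitudinal Treatment-Response Assessment for Brain Metastases
Version: 0.1.0
Authors@R:
    person("Response Assessment", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A response-assessment engine for longitudinal brain-metastases
    patient courses. Implements the RANO-BM overall response classification
    (CR/PR/SD/PD from target-lesion sums, non-target behaviour, new lesions,
    corticosteroid use, and clinical status) together with pluggable
    target/non-target lesion-designation policies (fixed baseline targets,
    sequential add/replace, and treatment-based designation), per-lesion and
    mixed-response reporting, distant-brain-failure extent/latency/velocity
    metrics (BMV and volumetric BMV), and a brain-specific-symptoms clinical
    status scale complementing the Karnofsky performance score. Ships
    programmatic hypothetical-scenario fixtures, a seeded stochastic course
    simulator, JSON/CSV readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
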