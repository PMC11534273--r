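Package: ctfmeta
Title: Metacognitive Analysis of Confidence-Weighted True-False Assessments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scoring and paired pre-post analysis of confidence-weighted
    true-false (CTF) knowledge assessments. Computes content-knowledge
    scores (summed CTF, percent CTF, binary percent correct), the five
    Dutke-Barenberg style metacognitive calibration indices (absolute
    accuracy, bias, confident-correct and confident-incorrect
    probabilities, discrimination), tie-corrected Wilcoxon signed-rank
    tests with Rosenthal effect sizes, per-item McNemar tests and
    confident-incorrect change metrics, and a synthetic paired-cohort
    generator with known latent knowledge and confidence-calibration
    structure for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
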