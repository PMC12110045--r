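Package: critdiv
Title: Divergence-Rate Detection of Critical Phase Transitions in
    Rate-Distortion Codebooks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects critical phase transitions in families of conditional
    distributions indexed by a control parameter, using a divergence rate:
    the per-step Kullback-Leibler divergence between consecutive codebooks,
    averaged over the input distribution.  Provides a Blahut-Arimoto
    fixed-point solver for discrete rate-distortion problems, closed-form
    high-beta solutions and exact first critical points for small state
    spaces, a z-score significance filter with a momentum-based noisy peak
    finder, and reproducible validation experiments: peak counts on random
    rate-distortion problems, a weak-universality comparison, a criticality
    heatmap for a three-state family, a clustering demonstration, and an
    ON/OFF ternary image-patch coding pipeline with a synthetic 1/f-noise
    image generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
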