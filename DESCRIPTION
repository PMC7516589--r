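Package: bistable
Title: Bistable Probability Models of Irrational Decision Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models irrational human decision making as the disagreement
    between a fast intuitive process (System 1) and a slow deliberative
    process (System 2) via bistable probabilities. Provides the scalar
    bistable probability map and its algebra, the equivalent
    positive-operator-valued (POV) bistable projections on the Bloch
    sphere, causal-strength and causal-power measures under bistability,
    accessible-information probability polytopes with exact volumes and
    the pure irrational information volume (PIIV) functional, Bell-Wigner
    inequality checks and attenuation sweeps, and a seeded Monte Carlo
    simulator of the two-system decision agent with parameter recovery.
    Includes a command-line interface for all computations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
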