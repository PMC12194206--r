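Package: figddm
Title: Drift Diffusion Modeling of Label Effects in Figure-Ground Object
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Fits a condition-dependent drift diffusion model to
    two-alternative figure-ground object-detection experiments in which
    word labels may precede bipartite displays.  Provides the Wiener
    first-passage-time density evaluated by small-time and large-time
    series expansions, closed-form choice probabilities and mean decision
    times, per-participant maximum-likelihood estimation with multi-start
    bounded optimization, a trial-design-aware simulator for balanced
    side-by-orientation-by-label designs, parameter-recovery experiments,
    and group-level parameter contrasts (mixed ANOVAs, increment tables,
    fastest-quantile response-time comparisons) together with
    quantile-based goodness-of-fit diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
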