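Package: dmtseq
Title: Treatment-Sequence Health-Economic Microsimulation for Relapsing
    Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level microsimulation of lifetime disease-modifying
    treatment (DMT) sequences in relapsing multiple sclerosis. Simulates
    annual EDSS transitions, relapses, adverse events and event-driven
    treatment switching through sequences of up to five treatment lines,
    accrues discounted costs (drug, other healthcare, societal) and
    quality-adjusted life years, and compares sequences by net health
    benefit. Includes a clinical sequence grammar, probabilistic
    sensitivity analysis with common random numbers, threshold searches
    for cost-neutral drug prices and efficacy-parity relative risks, and
    a synthetic parameter generator so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
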