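Package: detml
Title: Determinism Verification for Machine Learning Code
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for verifying that machine learning code is deterministic.
    Provides a rule-driven static analyzer for Python ML sources that detects
    missing random seeds, missing determinism flags and calls to operations
    known to be nondeterministic on GPUs; a runtime harness that trains a
    procedure repeatedly under random / seeds / deterministic setups and
    classifies it as bit-exact deterministic or not; a desk-scale simulator of
    floating-point reduction-order nondeterminism (the mechanism behind
    atomic-add nondeterminism on GPUs); and a hardware/software provenance
    manifest recorder with digests and scoped equality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
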