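Package: amlsim
Title: Simulation of AML Induction Chemotherapy in a Feedback-Regulated
    Hematopoiesis Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic two-compartment model of coupled healthy and
    leukemic hematopoiesis with feedback-regulated self-renewal, marrow
    crowding and log-kill chemotherapy terms. Simulates first-line acute
    myeloid leukemia induction under a single 7+3 course or 7+3 plus bone
    marrow evaluation with conditional 5+2 re-induction, sweeps grids of
    therapy-intensity combinations, and extracts clinical endpoints such as
    time to complete remission, remission duration, therapeutic width and
    under- and overtreatment regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
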