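Package: devtrans
Title: Cross-Species Translation of Neurodevelopmental Event Timings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for translating human foetal neurodevelopmental ages into
    rat postconceptional ages. Brain regions are clustered by developmental
    pace with a finite mixture of linear regressions fitted by an EM
    algorithm with random restarts, the number of groups is selected with a
    bootstrap information criterion (EIC), group-wise developmental pace and
    onset are compared with nested bootstrap-t tests under
    Benjamini-Hochberg correction, statistically indistinguishable groups
    are merged, and the resulting group-wise linear equations form a
    human-to-rat (and inverse) age translation model. Includes a synthetic
    event-table generator with known ground truth and a full reproducible
    analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
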