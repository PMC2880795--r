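Package: erpica
Title: Independent Component Decomposition and Classification of Event-Related Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A pipeline for discriminating clinical groups from multi-channel
    event-related potentials (ERPs): Infomax independent component analysis of
    group-level ERP matrices with projector-based spatial filters, sliding-window
    extremum (amplitude/latency) feature extraction from component time courses,
    wrapper forward feature selection with a cross-validated support vector
    machine, epoch-level artifact rejection, and pooled two-sample t statistics.
    Includes a synthetic ERP generator with known ground truth (source
    topographies, Gaussian-bump waveforms, group latency shifts) so the full
    pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
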