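Package: myotrace
Title: Quantification of Detrusor Smooth Muscle Organ-Bath Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing event-annotated isometric tension recordings
    from detrusor smooth muscle (DSM) strips in an organ bath. Quantifies
    spontaneous contractions by fitting two Gaussians to the amplitude
    histogram (amplitude, as percent of the strip's 60 mM KCl reference
    contraction) and by locating the main harmonic of the power spectrum
    (frequency). Extracts electric-field-stimulation (EFS) contraction
    amplitudes, builds duration-response curves, and dissects cholinergic
    from non-cholinergic components with atropine. Measures drug-evoked
    baseline tension changes and pre/post fold changes of spontaneous and
    EFS contractions, and compares control versus bladder-cancer cohorts
    with unpaired t-tests. Includes a seedable forward generator of
    synthetic organ-bath traces with known ground truth so that every
    estimator can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    minpack.lm,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
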