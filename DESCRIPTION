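Package: sphmap
Title: Response Mapping for In Vivo SynaptopHluorin Imaging and Enhancer
    Conservation Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for trial-structured widefield fluorescence
    imaging of presynaptic activity reported by synaptopHluorin in the
    piriform cortex: photobleaching correction against blank trials,
    windowed delta-F/F differential images, frequency-domain Gaussian
    band-pass filtering, trial averaging and pixel-wise significance
    mapping, followed by subregion quantification, stimulus-response
    curves and hierarchical clustering of odour-evoked response patterns.
    Also provides a sliding-window conservation profiler with
    conserved-element calling at VISTA-style parameters, a degenerate
    consensus motif scanner for T-box binding sites, a transgenic-line
    expression-rate tabulator, and a seeded synthetic-data generator that
    produces image stacks and aligned sequence pairs with ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
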