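Package: optoburst
Title: Simulation and Analysis of Optogenetically Evoked Network Bursts in
    Compartmentalized Neuronal Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse line-scan calcium-imaging recordings of
    two-compartment neuronal cultures under optogenetic (ChR2) stimulation,
    and a matched synthetic-data generator. The analysis pipeline converts
    fluorescence traces to dF/F, detects network bursts, builds
    peristimulus averages, and estimates inter-compartment transmission
    delays by normalized cross-correlation, classifying devices as
    unidirectional, asymmetric or symmetric. The simulator implements
    quorum-percolation burst ignition on random synaptic graphs,
    photo-activation of transduced neurons, CNQX pharmacology,
    calcium-indicator convolution and line-scan acquisition with
    stimulation-saturation masking, so every pipeline stage can be
    exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    zoo,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
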