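Package: hvcra
Title: Feed-Forward HVC-RA-LMAN Spiking Network Model and Slice
    Electrophysiology Analysis for Songbird Motor Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a feed-forward spiking network of the songbird
    song-motor pathway, in which a leaky integrate-and-fire RA projection
    neuron integrates precisely timed HVC burst input through log-normally
    distributed synapses, variable LMAN input through mixed AMPA/NMDA
    synapses with voltage-dependent magnesium block, and tonic inhibition
    scaled to the HVC drive.  Provides the rendition-to-rendition
    firing-rate correlation measure of motor variability, parameter sweeps
    over developmental strengthening-and-pruning of HVC-RA connectivity
    and over LMAN input properties, and a slice-electrophysiology analysis
    toolbox (single-fiber and maximal evoked-current estimation, synaptic
    input counting, NMDA:AMPA ratio inversion, F-I and spike-frequency
    adaptation analysis) exercised on built-in synthetic recording
    generators with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
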