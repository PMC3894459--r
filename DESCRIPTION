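Package: tonotopnet
Title: Tonotopic Spiking Network Simulator for Learning Dynamic
    Spectro-Temporal Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulator and analysis toolkit for a tonotopic
    spiking neural network with delayed lateral plastic connections that
    learns dynamic spectro-temporal sound features.  Provides a leaky
    integrate-and-fire network with an event-queued delay structure and
    bistable spike-driven plasticity at the lateral synapses; generators for
    noisy FM-sweep and synthetic formant-track stimuli; a two-phase
    exposure/probe experiment protocol; information-theoretic acuity metrics
    (specific information, stimulus-specific information, ROC/AUC on spike
    counts); a gammatone/ERB cochlear front end for real audio; and an
    analytical operator that predicts post-exposure lateral connectivity
    directly from stimulus spectro-temporal correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
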