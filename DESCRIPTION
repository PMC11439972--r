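Package: barrelsim
Title: Layered Barrel-Cortex Microcircuit Simulator with PV, SOM and VIP
    Interneurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and simulates a four-layer spiking model of a mouse
    barrel-cortex column with excitatory neurons and three inhibitory
    interneuron classes (parvalbumin-, somatostatin-, and vasoactive
    intestinal peptide-expressing cells). Neurons are leaky
    integrate-and-fire units with exponentially decaying postsynaptic
    currents; connectivity is pairwise Bernoulli with log-normal synaptic
    weights and delays, and synapses optionally carry Tsodyks short-term
    plasticity (depression and facilitation). The package derives model
    parameters from literature values (membrane time-constant adjustment,
    PSP-to-PSC conversion, interneuron apportionment, spatial integration of
    connection probabilities), fits short-term-plasticity parameters to
    PSP-amplitude trains by exhaustive grid search, calibrates synaptic
    weight scaling and background drive, generates background, cell-type-
    specific and transient thalamic inputs, and computes the activity
    statistics used for evaluation (population rates, pairwise spike-count
    correlations, CV ISI, peristimulus time histograms with peak extraction,
    and normalized stimulus-response curves with significance tests).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
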