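Package: bgspike
Title: Spiking Network Model of the Primate Basal Ganglia with Action-Selection Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction, simulation and benchmarking of a leaky
    integrate-and-fire network model of the monkey basal ganglia (striatal
    medium spiny neurons and fast-spiking interneurons, subthalamic nucleus,
    external and internal globus pallidus) driven by cortical and thalamic
    Poisson afferents.  Networks are realized stochastically from anatomical
    parameterizations (bouton counts, projection fractions, dendritic synapse
    locations), synapses follow alpha-function post-synaptic potentials with
    passive-cable dendritic attenuation, and tonic inputs are calibrated
    against physiological firing-rate constraints.  Includes deactivation
    (receptor-block) experiments, salience-grid action-selection benchmarks
    with efficiency/distortion metrics, circuit-disruption comparisons,
    thalamic (CM/Pf) input sweeps, and rate/variability/spectral analyses of
    spike records.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
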