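Package: bgselect
Title: Basal Ganglia Action-Selection Circuit Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Firing-rate neural mass model of action selection in the basal
    ganglia. Implements the direct (Go), indirect (NoGo) and hyperdirect
    pathways as coupled leaky-integrator populations with sigmoidal
    activation, winner-takes-all cortico-thalamic loops, dopaminergic and
    cholinergic neuromodulation, and a two-term thresholded Hebb rule for
    reward/punishment-driven learning of corticostriatal synapses. Provides
    trial simulation under tonic and phasic dopamine schedules, lesion
    experiments (subthalamic nucleus off, cholinergic interneuron clamped),
    multi-epoch training with stimulus noise, dopamine-level sweeps and
    latency-versus-stimulus-strength curves, plus a command-line interface
    for scripted experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
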