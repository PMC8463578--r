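Package: spikesam
Title: Spike Activation Maps for Interpreting Spiking Neural Networks
Version: 0.1.0
Authors@R: person("Spikesam", "Developers", role = c("aut", "cre"),
    email = "spikesam@example.org")
Description: Gradient-free, label-free visual explanations for spiking neural
    networks. Computes spike activation maps (SAM) from inter-spike-interval
    contribution scores recorded during forward simulation of leaky
    integrate-and-fire networks, together with the machinery needed to exercise
    the method end to end at desk scale: a discrete-time LIF simulator with
    batch normalization through time, Poisson rate coding, surrogate-gradient
    training and ANN-to-SNN conversion, Grad-CAM baselines (on a reference ANN
    and through surrogate gradients on the SNN), FGSM adversarial attacks, a
    synthetic labeled-shape dataset with ground-truth masks, and quantitative
    evaluation metrics (localization error, heatmap variance, normalized L1
    distance, mask localization score).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
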