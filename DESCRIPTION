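Package: bgutility
Title: Basal Ganglia Network Model of Dopamine and Serotonin in
    Reward, Punishment and Risk Based Decision Making
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates utility-based decision making in the basal ganglia.
    Provides an abstract risk-sensitive reinforcement-learning model (value,
    risk and utility functions with a softmax policy), a network model with
    three medium-spiny-neuron pools (D1R, D2R and D1R-D2R co-expressing)
    whose cortico-striatal weights are trained through sigmoidal dopamine
    gain functions, and STN-GPe-GPi-thalamus dynamics that perform action
    selection.  Serotonin levels enter as multiplicative gains on the three
    MSN pools, and Parkinson's disease ON/OFF medication states are modelled
    by clamping the dopamine prediction-error signal.  Harnesses for three
    behavioral experiments (risk sensitivity with safe/risky juice rewards,
    reversal learning under tryptophan depletion, probabilistic
    reward-punishment classification in PD), plus parameter sweep and
    genetic-algorithm fitting utilities and a YAML run-configuration layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
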