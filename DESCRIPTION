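Package: colonygames
Title: Social-Learning Dynamics of Task Allocation in Insect Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based simulation and analysis of a continuous-trait
    n-player task-allocation game for social insect colonies. Workers allocate
    effort between a homeostatic task, a thresholding task and inactivity;
    payoff-modulated social learning (softmax Wright-Fisher recruitment with
    Gaussian trait mutation) drives the population dynamics. The package
    classifies the resulting behavioural regimes (uniform activity, evolutionary
    branching into active and lazy sub-populations, full inactivity), provides
    an adaptive-dynamics layer (invasion fitness, selection gradients, singular
    strategies and their ESS/branching classification, streamline fields),
    quantifies decentralization losses via the relative colony efficiency
    (price of anarchy) and the social efficiency deficit against a
    differential-evolution social optimum, and supports culling experiments
    that probe homeostatic recovery after worker loss.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    mclust,
    pracma,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
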