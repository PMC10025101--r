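Package: echinovision
Title: Decentralized Vision and Visually Guided Taxis in Sea Urchins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Firing-rate network model of decentralized spatial vision in the
    long-spined sea urchin Diadema africanum. Screened photoreceptor groups
    distributed along the five ambulacra respond to angular light profiles on a
    circular arena wall through a rectified-cosine angular sensitivity kernel;
    they inhibit radial-nerve neuron groups, which in turn disinhibit excitatory
    oral-nerve-ring neurons. A population-vector readout of the oral nerve ring
    decides whether a stimulus is detected and in which direction the animal
    moves. The package generates isoluminant stimulus families (bar,
    difference of Gaussians, flanked bar, Haar, Morlet, and Hermitian wavelet
    profiles), solves the network to its fixed point, computes preferred
    directions and population vectors, simulates static and step-by-step taxis
    of cohorts of model animals, evaluates Rayleigh and V tests of circular
    statistics, and maps detection performance over the acceptance-angle and
    photoreceptor-spread parameter plane.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
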