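Package: antennaCSD
Title: Current Source Density Analysis of Multi-Electrode Electroantennograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Localizes odor-activated olfactory receptor neurons on insect
    antennae from electroantennogram (EAG) recordings taken at multiple
    proximo-distal positions. The funiculus surface is modeled as an unfolded
    cylinder or cone carrying rectangular current sources; the electrostatic
    forward solution yields a transfer matrix from compartmental current
    source density (CSD) to electrode potentials, and its inverse maps
    recorded EAG distributions back to CSD profiles. Includes EAG
    preprocessing and response metrics, center-of-mass localization,
    bias-characterization simulations (sub-compartment sources, electrode
    subsets, geometry sensitivity), one-dimensional cellular functional maps
    of the Drosophila melanogaster antenna built from sensilla counts and
    logit-normal spatial distributions, and a GC-EAD mode that integrates CSD
    responses within retention-time windows.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
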