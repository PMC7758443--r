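Package: mecwave
Title: Mechano-Electric Coupling and Calcium Waves in 1D Cardiac Myocyte Strings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A strongly coupled one-dimensional simulator of rabbit ventricular
    cardiomyocyte electromechanics. Single myocytes are discretised into 50
    calcium-release units (CRUs), each pairing a reduced ionic membrane model
    with a sarcomere mechanics model whose troponin-C calcium kinetics carry a
    strain-rate-dependent mechano-electric feedback. CRUs are coupled by
    compartmental calcium diffusion and resistive membrane-potential transfer;
    myocytes are chained by linear gap junctions and optionally loaded with
    active fibroblasts. Prescribed stretch protocols, pacing schedules and an
    extracellular-calcium sweep drive the model into calcium overload, and an
    analysis suite detects spontaneous calcium waves and delayed
    after-depolarisations, measuring wave velocity, amplitude, APD90,
    inter-cellular dyssynchrony and group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
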