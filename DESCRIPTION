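Package: freqresp
Title: Frequency-Response Analysis of Periodically Perturbed Molecular
    Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterizes the propagation of local periodic
    conformational perturbations through a protein from molecular dynamics
    trajectories. Provides discrete Fourier spectral-density estimation of
    atomic variables (Cartesian coordinates, backbone and side-chain
    dihedral angles, polar-contact distances), statistical detection of
    perturbed variables against a 1/f spectral background using one-sided
    Student-t prediction limits on the log-log spectrum, phase-angle
    clustering of collectively fluctuating elements on the doubled-angle
    plane, principal-component summaries of collective in-phase
    displacements with overlap and correlation against experimental
    structure pairs, and lead-lag transfer-function (magnitude Bode)
    fitting of frequency-dependent responses. Includes synthetic-data
    generators (1/f^beta noise, planted sinusoids, circular variables with
    rotamer jumps) and a coarse-grained restrained targeted-dynamics
    Langevin simulator so the full pipeline can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
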