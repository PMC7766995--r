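Package: dendritraj
Title: Trajectory Analysis of Charged Peptide Dendrimers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of molecular dynamics trajectories of charged
    peptide dendrimers and similar cationic macroions. Computes global and
    local structural descriptors (radius of gyration and gyration-tensor
    asphericity, Kirkwood hydrodynamic radius, terminal-group radius, radial
    density and terminal-group profiles, angular congregation coefficient),
    electric double-layer characteristics (radial and cumulative charge
    profiles, effective charge and charge renormalization, surface charge
    density, spherically symmetric Poisson potential and zeta potential,
    ion-pair and osmotic-ion accounting), geometric hydrogen-bond statistics
    with continuous lifetimes refined by spline interpolation, and NMR
    spin-lattice relaxation observables (first- and second-order Legendre
    orientational autocorrelation functions, spectral densities, reduced and
    susceptibility-representation 1/T1) including per-CH2-group analysis by
    topological distance along the side segment. Ships a coarse-grained toy
    dendrimer topology builder, a Brownian-dynamics toy integrator and a set
    of synthetic-data generators with closed-form ground truth for testing
    every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    bio3d,
    igraph,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
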