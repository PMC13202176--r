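Package: nucfold
Title: Nucleosome-Resolution Coarse-Grained Chromatin Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A physics-based, nucleosome-resolution coarse-grained model of
    chromatin in which epigenetic marks (histone tail acetylation, linker
    histone H1, BRD4 association) modulate nucleosome-nucleosome interactions.
    Builds bead-level nucleosome, chromatosome and fiber geometries from
    genomic specifications, generates the full interaction topology (harmonic
    and Morse bonds, DNA bending angles, a class-based Lennard-Jones pair
    matrix and Debye-Hueckel electrostatics), integrates Langevin dynamics
    with spherical-wall or periodic slab boundaries, performs umbrella
    sampling, and exports runnable LAMMPS inputs. Analysis tools cover contact
    maps and A/B-style compartments, insulation and compartmentalization
    scores, enhancer-promoter distances and structure clustering, MSD and
    anomalous diffusion exponents, DNA persistence length, sedimentation
    coefficients, nucleosome unwrapping equilibrium constants, WHAM potentials
    of mean force, slab coexistence densities, map-equation spatial domains,
    nucleosome clutches and stacking statistics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
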