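Package: tailscape
Title: Histone Tail-DNA Interaction Analysis: NMR Titrations, Biolayer
    Interferometry, and Trajectory Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of histone-tail accessibility on the
    nucleosome. Fits dissociation constants from NMR chemical-shift
    perturbation titrations under ligand depletion (per-residue quadratic
    isotherms with significance selection and outlier-screened
    aggregation), processes biolayer-interferometry sensorgrams
    (referencing, baseline alignment, Savitzky-Golay smoothing,
    steady-state hyperbolic fits), computes conformational metrics on
    molecular trajectories (radius of gyration, core-fitted RMSD,
    four-category secondary structure via Kabsch-Sander hydrogen bonds,
    voxel occupancy maps, Shrake-Rupley solvent accessibility, screened
    per-residue electrostatic tail-DNA energies), and provides
    sequence-derived extinction coefficients for proteins and duplex DNA.
    Includes generators for synthetic titrations, sensorgrams, ideal
    backbones, and collapsing-tail trajectory ensembles so every stage is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    minpack.lm,
    jsonlite,
    bio3d,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
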