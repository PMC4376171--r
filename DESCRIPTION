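Package: mdescape
Title: Ligand Escape Pathway Analysis for Multi-Copy Molecular Dynamics
    Trajectories
Version: 0.1.0
Authors@R:
    person("mdescape", "developers", email = "mdescape@example.org",
           role = c("aut", "cre"))
Description: Post-processing of locally-enhanced-sampling molecular dynamics
    simulations of ligand migration in globins. Reads PSF/PDB topologies and
    DCD trajectories carrying many simultaneous ligand copies, detects
    durable escapes past a minimum-distance protein-surface criterion,
    classifies escape portals by their flanking helix pair, records
    internal-cavity itineraries and inter-subunit crossings, and measures
    interfacial water-network persistence in dimeric hemoglobins. Includes a
    toy Langevin implementation of the 1/N copy-scaling contract of locally
    enhanced sampling and a scripted synthetic-trajectory generator with
    exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
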