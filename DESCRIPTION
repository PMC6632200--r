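Package: ionsite
Title: Ion Coordination Site Profiling from MD Trajectories and
    Voltage-Clamp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize extracellular cation coordination sites
    on membrane transport proteins. Profiles ion-residue contact
    frequencies from molecular dynamics trajectories (multi-model PDB,
    XYZ or tabular coordinates), extracts approach/dwell events at
    user-defined surface sites, summarizes ion coordination geometry and
    salt-bridge occupancy, scores alignment-column conservation at mapped
    reference positions, and analyzes two-electrode voltage-clamp
    current sweeps (window currents, deactivation, IV assembly, reversal
    potentials and semilog concentration fits). Includes synthetic-data
    generators with closed-form ground truth for validating every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
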