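Package: dermakin
Title: Transdermal Pharmacokinetics with Microdialysis Recovery and a
    Two-Layer Skin Diffusion Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for transdermal drug-delivery studies that
    combine skin-blood microdialysis sampling, Franz-diffusion-cell
    permeation experiments and Fickian diffusion modeling. Implements probe
    recovery calibration (gain/loss methods) and dialysate-to-tissue
    correction, cumulative permeation and steady-state flux analysis, a
    two-layer matrix-skin diffusion model with a partition interface and a
    capillary clearance sink (Crank-Nicolson solver plus diffusivity
    fitting), non-compartmental pharmacokinetic summaries, and simple
    membrane-trajectory metrics (time-average-reference RMSD, bilayer
    thickness, solvent carving). A seeded synthetic-data generator emulates
    the experimental designs so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
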