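Package: rcscreen
Title: Relaxed Complex Scheme Virtual Screening Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale analytics for structure-based virtual screening
    campaigns built around the relaxed complex scheme: persistent-contact
    hotspot analysis of protein-protein molecular dynamics trajectories,
    receptor conformer extraction by fixed-radius main-chain RMSD
    clustering, drug-likeness filtering of compound libraries with a full
    rejection audit (physico-chemical bounds, duplicates, PAINS and
    reactive substructures), multi-criteria triage of docking poses, and
    post-docking ligand stability scoring and ranking. A synthetic-data
    generator with planted ground truth stands in for molecular dynamics
    and docking engines so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
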