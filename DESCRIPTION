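Package: fcscreen
Title: Virtual Screening of ssDNA Ligands Against the Antibody Fc Segment
Version: 0.1.0
Authors@R: person("fcscreen", "maintainers", email = "fcscreen@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for rigid-body docking of single-stranded
    DNA ligands against an intact IgG antibody. Parses antibody-ligand
    complexes in PDB format, annotates immunoglobulin domain regions
    (VH/CH1/hinge/CH2/CH3/VL/CL and glycans), detects ligand-receptor
    interface contacts at configurable distance cutoffs, classifies binding
    modes, aggregates per-site binding frequencies, and computes base versus
    residue/monosaccharide contact propensities. Also fits 1:1 Langmuir
    association-dissociation kinetics to biolayer-interferometry sensorgrams
    (k_on, k_dis, K_D = k_dis/k_on, R squared) and implements the binding-call
    and competition-call decision rules. A synthetic-data module generates toy
    complexes with planted contacts, pose-score tables, and noisy sensorgrams
    with known kinetic truth, so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
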