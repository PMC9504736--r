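Package: pocketprofiler
Title: Structural Characterization and Ligand Interaction Profiling of
    Protein Binding Pockets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize the ligand-binding niche ("grotto") of a
    protein kinase domain from PDB coordinates and to profile its
    interactions with bound small-molecule ligands. Implements pocket
    extraction by author residue range, Kabsch-Sander secondary-structure
    assignment with grouping into helix/strand elements, Shrake-Rupley
    solvent-accessible surface area, geometric hydrogen-bond detection,
    residue polarity composition, secondary-structure-aware nonpolar
    contact networks with bimodality analysis of contact distances,
    protein-ligand interaction sweeps (hydrogen bonds, hydrophobic
    contacts, binding-locus residues), and global pairwise alignment of
    pocket sequences with Clustal-style conservation annotation. A
    synthetic-structure generator (ideal helices, strand pairs, toy
    complexes with planted contacts and hydrogen bonds) makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
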