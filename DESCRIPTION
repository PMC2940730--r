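Package: chaperonemodes
Title: Intrinsic Dynamics and Sequence Evolution of Hsp70 Chaperone Domains
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint analysis of the structure-encoded dynamics and the sequence
    evolution of the Hsp70 ATPase (nucleotide-binding) domain and its complexes
    with nucleotide exchange factors. Provides Gaussian and anisotropic elastic
    network models (GNM/ANM) with mobility profiles and mode-deformation
    overlap, Kabsch superposition and deformation vectors from PDB structures,
    a three-step multiple-sequence-alignment refinement, a relaxed Evolutionary
    Trace with level partitions and per-residue ranks, mutual-information
    co-evolution maps with gap as the 21st symbol, protein-protein interface
    characterization (4 Angstrom contacts, Shrake-Rupley solvent accessibility,
    salt bridges), and seeded synthetic-data generators (hinge-protein
    conformer pairs and tree-structured alignments with planted conservation
    and co-evolution) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    phangorn
Config/testthat/edition: 3
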