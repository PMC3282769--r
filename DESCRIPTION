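Package: ptcsig
Title: Sequence Signatures, Kinetics and Structural Metrics for
    Putrescine Transcarbamylase Annotation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rule-based discrimination of putrescine transcarbamylases (PTC)
    from ornithine transcarbamylases (OTC) using a structure-derived set of
    degenerate sequence signatures: the invariant STRT and HCLP active-site
    anchors, the lysine found two residues upstream of STRT in OTCs, the
    amine-specificity 230 loop versus the OTC SMG loop, a ~20-residue
    C-terminal extension, and the PTC-exclusive C-terminal helix-13
    signature scored with Chou-Fasman helix propensities.  Includes a
    degenerate-motif pattern engine, a seeded generator of PTC-like and
    OTC-like fixture sequences, Michaelis-Menten and inhibition-curve
    fitting with catalytic efficiency, a transcarbamylation equilibrium
    solver, and a small structural geometry kernel (Kabsch superposition,
    Shrake-Rupley solvent accessibility, interface burial, metal
    coordination geometry) for protein structures in PDB format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
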