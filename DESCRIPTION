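Package: RiboDelta
Title: Comparative Contact-Map Analysis of Homologous Ribonucleoprotein Structures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing atomic models of homologous ribonucleoprotein
    complexes, built around the delta-contact map: residue-pair heavy-atom
    contact counts at a 4 Angstrom cutoff are computed per interaction
    category (RNA-RNA, RNA-protein, protein-protein) for two models, residues
    are put in correspondence by deterministic global sequence alignment, and
    the entrywise count difference is reduced to residue-resolved gain/loss
    scores suitable for B-factor-encoded visualization. Includes cryo-EM
    model-quality filtering (per-residue Q-score and local resolution),
    Kabsch superposition and RMSD, per-residue displacement flags, nucleotide
    center-of-mass distances, substitution enumeration, mutation-site
    neighborhoods, a synthetic paired-model generator with planted ground
    truth, and an end-to-end comparison report with heatmap rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    bio3d,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
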