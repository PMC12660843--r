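Package: phabkit
Title: Antibody Engineering Toolkit for Labile Phospho-PTM Binders
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computational tools for engineering antibodies against labile
    post-translational modifications such as 3-phosphohistidine. Provides
    Kabat and IMGT variable-domain numbering with insertion codes, CDR
    grafting with Vernier-zone back-mutation planning, soft-randomization
    phage-library design (per-codon nucleotide mixtures, exact amino-acid
    distributions, stop templates, mutagenic oligo specs, seeded clone
    sampling), phage-selection pool analysis (substitution matrices,
    template detection, binding association), 1:1 Langmuir biolayer
    interferometry kinetics (simulation and global fitting of ka, kd, KD),
    ELISA standard-curve and four-parameter logistic utilities, and
    structural interface analysis (Kabsch superposition, hydrogen-bond,
    water-bridge, pi-pi and pi-cation contact detection under explicit
    geometric criteria, GXGX motif scanning, and Shrake-Rupley solvent
    accessible surface areas). Includes deterministic synthetic fixture
    generators so every analysis is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
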