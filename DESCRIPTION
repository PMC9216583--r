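Package: psnalign
Title: Protein Structure Networks, Conserved Interactions and Curation of
    Structure-Based Superfamily Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for annotating structure-based multiple sequence
    alignments of protein domain superfamilies. Builds residue-contact
    protein structure networks (PSNs) at the backbone (C-alpha, 7.5 Angstrom)
    and side-chain (4.5 Angstrom) levels, aligns them across members via the
    alignment columns and extracts absolutely conserved interactions (ACIs).
    Computes alignment quality statistics (gap percentages, conserved and
    highly conserved residue columns, secondary-structure conservation),
    pairwise C-alpha RMSD and sequence-identity matrices via rigid-body
    (Kabsch) superposition, and a UPGMA structural dissimilarity tree.
    Includes a k-means/elbow curation procedure that flags poorly aligned
    superfamilies and recommends trimming giant members, removing dwarf or
    structural-outlier domains, or splitting the superfamily, plus a
    deterministic synthetic toy-superfamily generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
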