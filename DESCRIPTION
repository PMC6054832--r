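Package: pocketmap
Title: Pharmacological Mapping of Protein Binding Sites from Ligand Contact Profiles
Version: 0.1.0
Authors@R: person("pocketmap", "developers", email = "pocketmap@example.org", role = c("aut", "cre"))
Description: Computes protein-ligand interaction fingerprints and
    distance-ramp contact-strength profiles from binding-site complexes,
    propagates the profiles through a master multiple sequence alignment
    using normalized Gonnet residue similarities, and derives
    pharmacological similarity matrices, neighbor rankings for target
    deorphanization, and average-linkage/UPGMA clustering trees with
    Newick export. Includes a synthetic-data module that generates toy
    complexes with prescribed geometry and alignments with planted
    pharmacological neighbors, so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
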