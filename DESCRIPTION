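Package: tunnelflex
Title: Exhaustive Side-Chain Rotamer Conformations of Protein Tunnels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Enumerates every collision-free ("valid") side-chain rotamer
    conformation of the amino acids adjacent to a protein tunnel or channel,
    using a sphere model of the structure, bounding-sphere broad-phase
    collision filtering, and Bron-Kerbosch maximal-clique enumeration on
    residue-level collision graphs and rotamer-level collision-free graphs.
    Local valid conformations found per clique are combined into global
    conformations by a pruned depth-first search. For each valid conformation
    the tunnel radii are recomputed as clearance along the fixed centerline,
    giving the per-conformation minimum bottleneck radius and, over all
    conformations, the maximum bottleneck: the largest spherical ligand that
    can pass through the flexibly deformed tunnel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
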