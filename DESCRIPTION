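Package: foldmatch
Title: Protein Structure Similarity Search with Compact Distance-Matrix
    Embeddings and a Learned Cluster Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained engine for tertiary-structure similarity
    search over collections of single protein chains. Each chain's
    alpha-carbon trace is compressed into a short rotation-invariant
    vector by bilinear down-sampling of its inter-residue distance
    matrix; the vectors are partitioned by k-means and served by a
    learned index in which a small feed-forward classifier routes a
    query embedding to its most promising clusters. Retrieved candidates
    are ranked by Euclidean embedding distance under a fixed candidate
    cap, and the top results are scored by an internal TM-align-style
    superposition engine reporting TM-score, RMSD, aligned residues and
    sequence identity. Includes readers for PDB and mmCIF single-chain
    files, offline identifier-mapping tables (PDB id and gene symbol to
    UniProt accession), a deterministic synthetic-structure generator
    (helix, strand, coil, perturbed families) for offline benchmarking,
    recall benchmarking against brute-force search, paged result
    expansion with session caching, and CSV export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
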