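Package: ensdist
Title: Distance-Geometry Analysis of Protein Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Superposition-free analysis of Calpha conformational ensembles from
    molecular dynamics trajectories or multi-model PDB files. Implements the
    distance root-mean-square deviation (dRMSD) dissimilarity, per-pair
    fluctuation (distance variance) and flexibility (distance range) matrices,
    the overall fluctuation statistic Theta, difference and mean-absolute
    difference distance matrices, k-means clustering of conformers in
    distance-matrix space with silhouette validation, classical
    multidimensional scaling embeddings, medoid and outlier identification,
    conformational-selection versus induced-fit diagnostics (Q(k) neighbor
    profiles, binding-cleft distance distributions with Gaussian-mixture fits,
    open-state fractions, cluster dwell-time kinetics) and RMSIP convergence
    checks, plus seeded synthetic-ensemble generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    mclust,
    stats,
    tools,
    utils,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
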