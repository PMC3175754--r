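Package: srds
Title: Sparse Representation of Deformable 3D Organ Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Spherical-harmonic decomposition of corresponded genus-0 organ
    surface meshes, structured (block) dictionary learning over the harmonic
    coefficients by orthogonal subspace pursuit, and block-sparse coding of
    new deformations, with a dual-layer (interior plus exterior wall)
    extension. Includes icosphere ray-casting surface correspondence,
    synthetic deformation-cohort generators with planted subspace structure,
    and the standard evaluation metrics (normalized reconstruction error,
    directed Hausdorff distance, sparsity statistics). ASCII mesh input and
    output in PLY, OBJ, OFF and STL formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
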