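Package: vlsmpipe
Title: Voxel-Based Lesion-Symptom Mapping of Auditory Temporal Processing Deficits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline linking auditory temporal-processing deficits to
    lesion anatomy: transformed up-down (n-down/1-up) adaptive staircase
    threshold estimation with simulated logistic observers, non-parametric
    behavioral statistics with the r = |Z|/sqrt(N) effect-size convention,
    control-referenced 2-SD deficit classification, voxelwise lesion-symptom
    mapping with the Liebermeister quasi-exact test and max-statistic
    permutation family-wise error correction, and post-processing of
    probabilistic tractography streamline-count volumes into group variability
    maps. Includes a synthetic cohort generator (coherent lesion blobs on a
    common 1-mm grid, latent observers, feature-structured error rates) with
    ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
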