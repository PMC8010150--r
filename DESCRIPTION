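Package: neosurf
Title: Neonatal Cortical Surface Reconstruction from Tissue-Labelled MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs white-matter and pial cortical surfaces from a
    T1-weighted-like intensity volume and a co-registered tissue label volume
    (background/CSF/GM/WM), with emphasis on small neonatal brains where
    sulcal cerebrospinal fluid is invisible because of partial volume effects.
    Provides topology-guaranteed white-matter mesh extraction (homotopic
    collapse of an enclosing ellipsoid), icosahedral mesh resampling to a
    fixed vertex count, curvature-driven homotopic skeletonization of the
    grey-matter/CSF union to hypothesize buried sulcal CSF, Laplacian-field
    streamline expansion of the white-matter surface into an intermediate
    pial surface, intensity-gradient surface refinement, and surface
    morphometry (cortical thickness, surface smoothing, sulcal depth,
    landmark distances, template selection by sulcal-depth correlation).
    Includes a synthetic phantom generator with analytic ground truth so the
    whole pipeline is testable without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
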