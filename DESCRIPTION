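Package: petbench
Title: Radionuclide Image-Quality Benchmarking for Preclinical PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing PET radionuclides (18F, 64Cu, 68Ga, 44gSc)
    on equal footing in preclinical phantom studies. Provides radionuclide
    decay physics (positron yields, decay-equalized acquisition planning,
    isotope-mixture evolution), parametric models of the NEMA NU 4-2008
    image-quality, Derenzo resolution and NEC count-rate phantoms with
    voxelization into activity and attenuation maps, an image-domain
    degradation simulator (positron-range and system blurring, scatter
    background, Poisson counting noise, optional Gibbs ringing), and the
    NEMA-style metric suite: uniformity and percent standard deviation,
    recovery coefficients, spill-over ratios, Derenzo rod contrast, and
    noise-equivalent count rates extracted from synthetic sinograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
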