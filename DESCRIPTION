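Package: trabequant
Title: In Vivo Trabecular Bone Microarchitecture Quantification from GRE MRI and PET
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies trabecular bone microarchitecture from gradient-echo MR
    images of the knee: bone volume fraction (BVF) mapping, Chan-Vese bone
    delineation with cortical stripping and named ROI construction,
    aperture-map morphometry (BVF, Tb.Th, Tb.Sp, Tb.N), PET standardized
    uptake value (SUV) quantification with hypermetabolic classification,
    per-bone log-Euclidean poly-affine PET-to-MR fusion, and group-comparison
    reporting (percent differences, Student's t-tests). Includes a synthetic
    phantom and cohort generator with analytic ground truth so the whole
    pipeline is testable without patient data, and a minimal NIfTI-1 reader
    and writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
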