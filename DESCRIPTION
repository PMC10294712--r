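Package: petcbda
Title: Compressive Big Data Analytics for PET Binding-Potential Classification
Version: 0.1.0
Authors@R: person("PET-CBDA", "Maintainers", email = "maintainers@petcbda.org",
    role = c("aut", "cre"))
Description: Voxel-level analysis of parametric PET non-displaceable binding
    potential (BP_ND) maps for case/control classification. Provides a
    synthetic two-tracer cohort generator (Carfentanil mu-opioid and
    Raclopride dopamine D2/D3 designs), NIfTI-1 volume input/output, masking
    and DVR threshold/consistency voxel reduction, a cross-validated stacked
    ensemble with non-negative least-squares meta-weighting, the CBDA
    subsample-ensemble-rank feature selection procedure with nested top-k
    validation and replication merging, classification metrics with exact
    binomial confidence intervals, and ROI-level frequency reporting, plus a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
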