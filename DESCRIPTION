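Package: wmpvs
Title: Quantification of White-Matter Perivascular Spaces from Paired T1/T2 MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated detection, counting and grading of white-matter
    perivascular spaces (WM-PVS) on paired T1-/T2-weighted brain MRI.
    Implements the full subject-level pipeline (rigid T2-to-T1 registration by
    normalized mutual information, adaptive non-local-means denoising,
    polynomial white-matter intensity uniformization anchored at a fixed
    median, one-voxel mask erosion, local intensity-difference mapping,
    thresholding, per-axial-slice 8-connected cluster counting, a 5-point
    grade from the maximum per-slice count, white-matter-normalized volume
    and an enlargement criterion), a synthetic MRI phantom and cohort
    generator with ground truth for validation, and the nonparametric
    case-control statistics used to compare groups (Mann-Whitney,
    Kruskal-Wallis, chi-square/Fisher with an expected-count selection rule,
    Spearman correlation, Shapiro-Wilk).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
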