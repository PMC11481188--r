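Package: agecourse
Title: Longitudinal Transcriptome Trajectories and Tipping-Point Analysis of Cardiac Aging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal (age-continuous) bulk
    transcriptome studies of cardiac aging. Detects co-expression modules
    with a weighted correlation network (soft-thresholded adjacency,
    topological overlap, hierarchical module detection, eigengene-age
    correlation), performs directional pathway enrichment with Fisher's
    exact test, Benjamini-Hochberg correction and an activation z-score,
    selects linear versus quadratic age trajectories by the extra
    sum-of-squares F test and extracts the quadratic vertex ("tipping
    point") per transcript and per pathway, estimates the onset and fast
    phase of sigmoidal histology signals (e.g. glycosaminoglycan staining
    fractions) by the tangent method on a 4-parameter logistic, and
    assembles an ordered event timeline with human-equivalent ages. A
    synthetic-cohort generator with planted ground truth (negative-binomial
    counts over latent flat, linear or quadratic module signals) makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    edgeR,
    fgsea,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
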