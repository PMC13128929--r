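Package: hyaloidr
Title: Quantification of Hyaloid Vessel Regression from Flatmount Images and
    SORT-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated quantification of postnatal hyaloid (vitreous body)
    vessel regression and retinal angiogenesis from multi-channel
    immunofluorescence flatmounts, together with the matching plate-based
    single-cell (SORT-seq) analysis. Imaging tools segment nuclei (IsoData
    thresholding plus watershed), build a solid CD31 vessel mask, classify
    endothelial, pericyte and other nuclei by mask membership and nuclear
    circularity, compute background-corrected marker intensities and
    positive areas, call TUNEL puncta (Yen thresholding plus watershed),
    reduce the vessel mask to a skeleton graph of branch-to-branch segments,
    and flag regressing segments from linear TUNEL clusters with
    discontinuous CD31. Retina tools compute radial vascular expansion from
    the minimum-area enclosing ellipse and vascular density. The SORT-seq
    pipeline covers plate-depth normalization, UMI and mitochondrial QC,
    marker-rule cell typing, log-normalization, logistic-regression
    likelihood-ratio differential expression, hypergeometric gene-set
    enrichment and marker-panel screens. Seeded synthetic-data generators
    render ground-truthed flatmount images and plate-structured UMI count
    matrices so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
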