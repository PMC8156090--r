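Package: lesioncog
Title: Lesion-Network Overlap Mapping of Cognitive Deficits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how segmented brain lesions (resection cavities,
    contrast-enhancing tumor, T2/FLAIR hyperintensity, amino-acid PET
    positive tissue) overlap atlas-defined functional network nodes and
    white-matter tracts, screens those overlaps against cognitive test
    scores with a tie-corrected Kendall tau-b mass-univariate analysis
    under Bonferroni control, derives normative deficit thresholds from a
    matched healthy cohort, and fits node-augmented logistic models of
    clinically relevant impairment evaluated by contingency tables and
    ROC analysis. A synthetic-cohort module generates atlases, lesion
    masks, PET volumes and cognitive scores with planted effects so the
    entire pipeline is verifiable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
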