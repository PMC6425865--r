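Package: gliomig
Title: Quantification of Immunohistochemistry, Cell Migration and Spheroid
    Invasion Assays in Glioma Research
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of the quantification chain used in
    tissue-microarray and migration studies of pediatric gliomas: DAB
    immunohistochemistry positivity scoring of tissue cores (manual composite
    and digital positive-pixel scores with low/high dichotomization),
    contingency-table association testing (uncorrected Pearson chi-squared and
    the Freeman-Halton r x c Fisher exact test), 2D cell-track migration
    analytics (velocity, directionality, rose summaries, corrected total cell
    fluorescence), and 3D spheroid migration indexing from time-lapse masks.
    Seeded synthetic generators for cohorts, stained core images,
    persistent-random-walk trajectories and spheroid series make every stage
    verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    png,
    EBImage,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff
Config/testthat/edition: 3
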