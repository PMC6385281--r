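Package: mbdfam
Title: Genealogical Analysis and Segregation Simulation for Familial
    Malignant Blood Disorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the familial aggregation of malignant blood
    disorders (leukemias, lymphomas, myeloma and myeloproliferative
    neoplasms) in pedigrees.  Reads LINKAGE/PED-style pedigrees with a
    companion phenotype table, enumerates affected relatives of each proband
    along vertical and oblique kinship lines, classifies patrilineal and
    matrilineal affiliation, standardizes probands to monoparental lines and
    scores the observed-versus-expected distribution of affected relatives
    across the four proband-sex by parental-line groups.  Includes the
    Haldane-Smith birth-order test with an exact enumeration oracle, a
    Wilcoxon signed-rank control, a diagnosis co-/contravariation screen,
    cohort frequency statistics, and a forward-time pedigree simulator of a
    parent-of-origin imprinting plus mother-son microchimerism segregation
    model that generates the three canonical patterns of affected-relative
    distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
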