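Package: prage
Title: LD-Aware Parametric Gene-Set Enrichment for Genome-Wide Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Competitive gene-set enrichment testing for genome-wide association
    studies from SNP-level p-values. Gene-level summaries are corrected for
    linkage disequilibrium through an effective gene size derived from
    block-wise compound-symmetric covariance models selected by AIC, and gene
    sets are tested with a heterogeneous-variance Welch statistic with
    Satterthwaite degrees of freedom, avoiding permutation. Includes the
    Z-statistic (PAGE-style) baseline, Storey q-values, marker quality control,
    an additive association scan, SNP-to-gene mapping, a block-LD genotype
    simulator, and a size/power study driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    fgsea,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
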