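Package: triploase
Title: Parent-of-Origin Effects, Allele-Specific Expression and Methylation
    in Reciprocal Triploid Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis toolkit for dissecting parent-of-origin effects (POE)
    in reciprocal diploid/triploid/tetraploid hybrid series. Provides factorial
    differential-expression contrasts separating POE, ploidy and hybridity;
    a dosage-aware allele-specific expression (ASE) test against the triploid
    2:1 parental null with SNP-to-gene aggregation and Benjamini-Hochberg
    correction; reciprocal-cross imprinting calls (PEG/MEG) that discriminate
    parent-of-origin bias from cis (genotype-attached) bias; allele-specific
    DNA-methylation (ASM) statistics in CG/CHG/CHH contexts with metagene
    profiles and a gene-body-methylation/expression association; diurnal
    expression summaries over Zeitgeber-time series with 2^-ddCt
    quantification; and a synthetic-data generator that emulates the full
    study design with planted ground truth for every downstream test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    rtracklayer,
    BiocGenerics,
    GenomeInfoDb
Suggests:
    e1071,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
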