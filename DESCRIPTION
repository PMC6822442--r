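Package: wssgwas
Title: Weighted Single-Step Genome-Wide Association for Repeated Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Weighted single-step GWAS (wssGWAS) for livestock populations in
    which many animals are phenotyped but only a subset is genotyped. Fits a
    repeatability animal model by average-information REML, predicts genomic
    breeding values by single-step GBLUP with a blended pedigree-genomic H
    relationship matrix, iteratively back-solves SNP effects from breeding
    values and re-weights markers by their variance contribution, and reports
    the share of additive genetic variance captured by fixed-width genomic
    windows together with QTL-region selection, merging and extension rules.
    Includes a pedigree/gene-dropping simulator for repeated-record phenotypes,
    marker quality control (call rate, minor allele frequency, exact
    Hardy-Weinberg test), and text PLINK PED/MAP input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Matrix, methods, stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
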