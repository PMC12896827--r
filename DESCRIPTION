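Package: kaspanel
Title: Genome-Wide SNP Screening, KASP Assay Design and Diversity
    Validation for Conservation Marker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for developing Kompetitive Allele-Specific PCR (KASP)
    SNP marker panels from whole-genome resequencing data, as used in
    conservation genetics of the Yangtze finless porpoise. Implements
    GATK-style hard filtering of cohort VCFs, biallelic and isolation
    (100 bp window) selection, VCFtools-style minor-allele-frequency,
    missingness and Hardy-Weinberg prefiltering, polymorphism
    information content (PIC) band selection, evenly distributed panel
    subsampling, allele-specific primer construction with FAM/VIC
    tails, and per-locus diversity statistics (Na, Ne, Shannon index,
    Ho, He, F_IS, major allele frequency, PIC, HWE tests). A synthetic
    data module generates reference sequences, annotated cohort VCFs
    with planted filter violations, and genotype matrices with known
    parameters so the whole pipeline is testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
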