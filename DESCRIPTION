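Package: cosegmap
Title: Mapping-by-Sequencing of Recessive Trait Loci via Windowed
    Co-Segregation Proportions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes monogenic recessive trait loci from a four-library
    family sequencing design (a homozygous parent, a heterozygous parent,
    and phenotype-sorted pools of homozygous and heterozygous offspring).
    Informative parental variants are selected from a multi-sample VCF,
    the proportion of variants co-segregating with the phenotype is
    computed in sliding genomic windows at genome-wide and fine scale,
    candidate intervals are called, triaged by supporting variant counts
    and annotated at codon-level consequence resolution against a gene
    annotation and genome sequence. A Mendelian cross simulator with
    recombination, pooled-depth genotype-call noise and fixture emission
    (VCF/BED/GFF3/FASTA) provides desk-scale inputs with the statistical
    structure the scan assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
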