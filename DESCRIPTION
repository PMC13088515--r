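Package: haplolethal
Title: Detection of Recessive Lethal Haplotypes from Phased Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discover haplotypes harbouring recessive lethal alleles
    in pedigreed livestock populations. Implements a sliding-window scan of
    phased SNP-chip genotypes for haplotypes with a deficit of homozygous
    animals relative to the Hardy-Weinberg expectation (exact binomial test,
    Bonferroni correction), classification of matings into risk categories
    with contrasts of insemination success, stillbirth rate and juvenile
    mortality, and a carrier-concordance filter that nominates candidate
    causal variants from sequenced-sire genotypes. A gene-drop simulator
    generates pedigrees, phased genotypes with a planted lethal haplotype,
    and mating and foal records, so the whole pipeline is testable end to
    end without proprietary studbook data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
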