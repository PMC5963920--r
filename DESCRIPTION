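Package: autozyg
Title: Autozygosity Mapping and Recessive Variant Prioritization in
    Consanguineous Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects runs of homozygosity from SNP-array genotypes of a
    nuclear family, delineates candidate autozygous (identical-by-descent)
    loci shared by affected siblings and absent from unaffected members,
    filters loci by genetic length, and prioritizes homozygous rare variants
    within the mapped loci under a recessive segregation model. Includes a
    pedigree simulator with first-cousin consanguinity, Haldane-model
    recombination and an implanted causal autozygous region, so every stage
    of the mapping can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    IRanges,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
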