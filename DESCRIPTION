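Package: minmark
Title: Minimal SNP Marker Sets for Genebank Accession Fingerprinting
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and deploying minimal SNP marker sets (MMS)
    for molecular barcoding of genebank accessions. Reads genotype call
    matrices in the delimited dialects common to KASP and array exports,
    applies the call-rate and minor-allele-frequency quality filters used in
    genebank genomics, greedily selects the fewest markers whose joint
    fingerprints discriminate a collection, fingerprints and matches
    accessions for regeneration quality control, computes per-marker
    informativeness statistics (MAF, expected and observed heterozygosity,
    polymorphic information content, pairwise LD), and quantifies panel
    robustness under simulated marker failure. Includes a seed-reproducible
    synthetic genotype generator emulating genebank collections of inbred
    lines: diverged subpopulations, planted duplicates, pedigree-related
    breeder lines, wild populations, residual heterozygosity and missing
    calls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
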