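Package: rilseg
Title: Recombinant Inbred Line Simulation and Phenotype-Conditioned
    Variant Filtering
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying causal sequence variants in recombinant
    inbred line (RIL) panels of selfing organisms such as Caenorhabditis
    elegans. Simulates RIL genomes under repeated self-fertilization
    (Poisson crossovers with a Haldane or obligate-chiasma model, residual
    heterozygosity decay, de novo mutation), builds strain-by-variant
    presence/absence matrices from VCF-style variant calls, applies
    phenotype-conditioned segregation filters to nominate candidate causal
    variants, scans alignments for soft-clipped and chimeric read
    signatures of structural-variant breakpoints, and computes the
    behavioral statistics (thermotaxis bias, grid exploration count,
    chemotaxis index) used to classify strains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
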