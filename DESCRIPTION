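Package: sweepscape
Title: Detection and Characterisation of Partial Selective Sweeps at
    Insecticide-Resistance Loci from SNP Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterising evolutionarily
    independent partial selective sweeps at insecticide-resistance loci
    (such as the voltage-sensitive sodium channel and glutathione
    S-transferase gene clusters of Aedes mosquitoes) from multi-sample
    SNP genotype data.  Implements latent-factor-adjusted genome scans
    with false-discovery-rate control, homozygous-haplotype background
    screening, windowed Tajima's D, nucleotide diversity, genotype-r2
    linkage disequilibrium and Weir-Cockerham FST with delta contrasts
    between swept and wild-type cohorts, long-range linkage-network
    scoring, read-depth copy-number ratios, f3 admixture tests with
    block-jackknife errors, and PCA projection of admixed individuals.
    Includes a synthetic-data generator with Balding-Nichols population
    structure, embedded partial sweeps, copy-number variation and
    admixture, so every pipeline stage is verifiable against ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
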