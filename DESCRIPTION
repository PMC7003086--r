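Package: splitdrive
Title: Forward Simulation and Quantification of a Split Homing Gene Drive
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seeded forward stochastic simulator of a split CRISPR homing gene
    drive segregating at two X-linked loci (white and yellow) in Drosophila
    melanogaster, together with the quantification pipeline used to read
    germline cleavage, homing and resistance-allele frequencies out of scored
    cross progeny. Models promoter-specific germline cut/HDR/NHEJ rates,
    maternal Cas9 protein carryover (shadow drive), embryonic versus germline
    cleavage timing, somatic mosaicism penetrance, and multi-generation
    resistance-allele accumulation. Also provides exact Punnett-square
    calculators and deterministic spread recursions for rescue-based drive
    architectures with lethal biallelic mosaicism, and a cut-site indel
    classifier for amplicon sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
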