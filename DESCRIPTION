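Package: magicmap
Title: Simulation and QTL Mapping for Eight-Way MAGIC Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of multiparent advanced generation intercross
    (MAGIC) populations (funnel crossing, meiosis, gamete-killer and zygote
    viability selection, genotyping error, multiallelic trait models), hidden
    Markov model founder-ancestry inference, population bin-map construction,
    SNP-level association and bin-level multiallelic linkage scans with
    permutation thresholds, segregation-distortion and recombination-landscape
    scans, and founder allele-effect ranking by Duncan's multiple range test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
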