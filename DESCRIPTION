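Package: pollenkiller
Title: Modeling and Analysis of Sporophytically Gated Pollen-Killer Systems
Version: 1.0.0
Authors@R: person("Pollenkiller", "Developers", email = "pollenkiller@example.org",
    role = c("aut", "cre"))
Description: Tools for studying gametophytic pollen-killer loci whose activity is
    gated by unlinked sporophytic partner loci (dominant activators or
    suppressors), as found in indica-japonica rice hybrids. Computes expected
    genotype frequencies under testcross, selfing and single-seed-descent
    designs with a male transmission parameter k, estimates k from progeny
    counts with exact binomial confidence intervals, tests segregation ratios
    (Pearson and exact multinomial), simulates multilocus populations forward
    in time with recombination and gamete-stage selection to demonstrate
    pseudo-linkage between unlinked interacting loci, predicts pollen-fertility
    phenotypes for multilocus sporophyte genotypes, and fine-maps causal loci
    from recombinant breakpoint panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
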