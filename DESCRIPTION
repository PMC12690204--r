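Package: noncodeq
Title: Equilibrium Noncoding Genome Fraction Under Structural Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic model of noncoding genome-size evolution on an idealized
    circular genome. Computes exact neutrality probabilities for structural
    mutations (duplications, deletions, inversions) and small mutations (point
    mutations, short indels) by uniform-breakpoint counting, the effective
    fitness (robustness) of a genome under the full mutation spectrum,
    Wright-Fisher fixation probabilities of genome-size-changing mutants, the
    per-type fixed-length fluxes and their bias, and solves for the equilibrium
    noncoding size and fraction as a function of population size, mutation
    rate, mutational bias, and coding architecture. Includes independent
    exhaustive-enumeration and forward Wright-Fisher simulation oracles, a
    species-table comparison layer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
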