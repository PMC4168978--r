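Package: recombdyn
Title: Wright-Fisher Dynamics with Recombination on Rugged Fitness Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of haploid populations evolving on tunably
    rugged fitness landscapes (Rough Mount Fuji, House of Cards, NK), with a
    configurable fraction of the population reproducing by uniform-crossover
    recombination. Provides a finite-population Wright-Fisher engine, a
    deterministic infinite-population engine with a compensated high-precision
    mode, fitness seascapes (stochastic landscape resets), diversity and
    trapping observables, and a paired-ensemble harness for quantifying the
    transitory adaptive advantage of recombination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
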