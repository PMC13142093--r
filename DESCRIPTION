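Package: chromocycle
Title: Cell-Cycle Simulation of SMC-Driven Chromosome Segregation in a Minimal Cell
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the chromosome of a minimal bacterial cell (JCVI-Syn3A,
    543 kbp) across its 105-minute cell cycle as a replicating circular
    bead-spring polymer (10 bp per bead) confined by a growing and dividing
    membrane. Chromosome loops are extruded by stochastic SMC (structural
    maintenance of chromosomes) motors on a 1D lattice with blocking,
    bypassing, dissociation and replisome interactions; topoisomerase strand
    passage is emulated by energy minimisation with a lowered excluded-volume
    barrier; conformations evolve by overdamped Brownian dynamics with a
    swelling relaxation step. Includes DNA replication by the train-track
    model, ribosome crowders, boundary-particle membranes, in-silico 3C
    contact maps with Knight-Ruiz matrix balancing, contact-probability
    curves, and a daughter-chromosome partitioning statistic.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
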