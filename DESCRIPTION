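Package: burstinfo
Title: Energy Dissipation and Information Transmission in Bursty Gene Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous-time Markov chain models of a transcriptionally bursting
    gene locus regulated by cognate and noncognate activators. Computes stationary
    distributions, entropy production (energy dissipation per burst cycle),
    transcriptional sharpness, precision and specificity, the information
    transmission rate between activator concentration and transcriptional output,
    and sequential-probability-ratio-test decision times. Includes an evolutionary
    parameter-sweep engine that traces achievable-region boundaries for metric
    pairs under equilibrium (detailed-balance) or nonequilibrium sampling, an
    exact Gillespie simulator used as a brute-force oracle and synthetic-data
    generator, and binding-site perturbation analyses that separate equilibrium
    from nonequilibrium circuits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
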