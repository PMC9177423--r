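Package: clonaldyn
Title: Lifelong Dynamics of Clonal Haematopoiesis from Serial VAF Data
    and Single-Colony Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the lifelong kinetics of mutant haematopoietic stem
    cell clones. Fits a hierarchical Bayesian beta-binomial logistic
    growth model to serial variant-allele-fraction (VAF) measurements,
    estimates technical sequencing overdispersion from replicate data,
    back-extrapolates fitted trajectories to the age at clonal onset
    under a two-phase Wright-Fisher growth model, and reconstructs
    historical clone sizes from time-calibrated single-colony somatic
    phylogenies via coalescent skyline estimation with biphasic growth
    and deceleration metrics. Includes a Wright-Fisher simulator of
    clone histories, sequencing counts and colony trees so the full
    pipeline is testable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
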