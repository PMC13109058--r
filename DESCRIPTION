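Package: haplosel
Title: Haplotype-Based Selection Scans and Polygenic Adaptation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Selection inference from phased, ancestral-allele-polarized
    haplotype panels. Computes extended haplotype homozygosity (EHH)
    decay curves, integrated haplotype homozygosity (iHH) on the genetic
    map scale, and frequency-bin-standardized integrated haplotype
    scores (iHS). Tests for polygenic adaptation with trait-integrated
    haplotype scores (tiHS) polarized by GWAS effect direction against a
    covariate-matched resampling null, with empirical two-sided p-values
    and Benjamini-Hochberg adjustment. Reconstructs allele-frequency
    trajectories and epoch-wise selection coefficients under a
    discretized Wright-Fisher hidden Markov model, and aggregates them
    into population-average polygenic-score trajectories. Includes a
    forward-in-time Wright-Fisher simulator with recombination and
    selective sweeps that generates every input format the pipeline
    consumes, so all stages are testable end to end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    vcfR,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
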