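Package: famsvd
Title: Family-Based Mixed Models via Spectral Reparameterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian and frequentist variance-component analysis of
    family-based phenotype data. Computes kinship and additive genetic
    relationship matrices from pedigrees, reparameterizes the correlated
    polygenic random effect through a per-family spectral (singular value)
    decomposition of the relationship matrix so that random effects become
    independent, and estimates variance components and narrow-sense
    heritability by purpose-built MCMC samplers for Gaussian and
    Bernoulli-logit traits. Includes pedigree simulators for standard
    family designs, a spectrally rotated REML/ML reference estimator, and
    an exporter that writes ready-to-run BUGS/JAGS model and data files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
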