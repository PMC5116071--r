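Package: multiherit
Title: Heritability Analysis of Multidimensional Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and inference for the SNP heritability of
    multidimensional (vector-valued) phenotypes. Implements a moment-matching
    (multivariate Haseman-Elston) estimator of the genetic and environmental
    covariance matrices with closed-form standard errors, Wald and permutation
    tests, and covariate projection; restricted maximum likelihood ACE variance
    component models with family-block bootstrap for twin and sibling designs;
    genetic relationship matrix construction from PLINK genotypes with quality
    control filters; and the Laplace-Beltrami spectrum ("Shape-DNA") shape
    descriptor pipeline that turns anatomical surface meshes or label volumes
    into such multidimensional traits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
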