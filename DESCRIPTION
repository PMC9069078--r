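Package: lfadmix
Title: Likelihood-Free Estimation of Admixture Proportions from Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scalable inference of individual admixture proportions and
    ancestral allele frequencies from biallelic genotype matrices under the
    structure/admixture model. The individual allele frequency matrix is
    estimated by latent subspace estimation (top eigenvectors of a
    genotype-derived operator, computed matrix-free with finite-alphabet
    accelerated multiplications) and factorised into constrained factors by
    truncated alternating least squares. Includes a supervised mode driven by
    reference allele-frequency panels, generative simulators under the
    Pritchard-Stephens-Donnelly and one-dimensional spatial models,
    permutation-matched accuracy metrics, and PLINK bed/bim/fam input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    stats,
    utils,
    tools,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
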