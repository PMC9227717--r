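Package: mntox
Title: Factorial Differential Expression and Brain Activity Mapping for
    Manganese Toxicity Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for two-by-two factorial (genotype by
    treatment) transcriptome studies of metal toxicity in zebrafish and
    similar models. Implements a negative-binomial GLM differential
    expression engine with median-of-ratios normalisation, dispersion
    trend fitting and empirical-Bayes shrinkage, and Wald tests of
    arbitrary contrasts; classifies genes into toxicity,
    increased-sensitivity (synergistic versus additive) and mutant-effect
    (rescued versus persistent) groups from the four standard contrasts;
    performs ontology enrichment by the term-for-term hypergeometric and
    parent-child-union methods on OBO ontologies with true-path
    annotation propagation; maps group differences in registered 3D image
    stacks by voxel-wise permutation testing with FDR masks summarised
    over anatomical region atlases; and generates synthetic count
    matrices, image volumes and qPCR Ct tables with machine-readable
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
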