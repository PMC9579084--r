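Package: inbuiltr
Title: Rubric-Mapped Latent Semantic Spaces for Automated Summary Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds latent semantic analysis (LSA) spaces from lemmatized
    corpora (log-entropy weighting, truncated singular value decomposition)
    and transforms them with the Inbuilt Rubric method: assessment-rubric
    concepts are mapped to unit vectors, assembled into a change-of-basis
    matrix together with randomly drawn standard-basis fill columns,
    orthogonalized by Gram-Schmidt under a fidelity gate, and used to rotate
    the space so that its leading coordinates score concept coverage of
    projected documents. Includes the bifactor variant that adds a general
    knowledge dimension estimated from split-descriptor factor loadings, a
    psychometric validation battery (two-way mixed intraclass correlations,
    paired contrasts, Horn's parallel analysis, exploratory factor analysis
    with oblimin rotation, standardized-beta regression, and unweighted
    least squares confirmatory factor and structural equation models with
    cross-loadings), and seeded generators for synthetic topic corpora,
    rubrics, summaries with known concept coverage, and simulated raters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
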