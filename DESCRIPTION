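Package: methpattern
Title: Sign-Constrained Bayesian Mixture Patterns for Small-Sample
    Differential Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects sex-discordant DNA methylation trajectory patterns
    across three tissue types from arrays with very few samples per group.
    Probes are clustered into nine sign-defined trajectory shapes per sex
    stratum by a constrained Bayesian mixture model fitted with a
    partially-collapsed Gibbs sampler; differential probes are selected by
    Bayesian q-values on posterior null-pattern probabilities.  Companion
    stages provide beta/M-value transforms, per-probe one-way ANOVA
    prefiltering, a moderated t/F linear-model comparison with
    empirical-Bayes variance shrinkage, univariate Cox proportional-hazards
    screening of candidate genes, ground-truth simulators for every stage,
    and end-to-end pipeline orchestration with reproducible manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
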