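Package: riskbn
Title: Nonlinear Risk Factor Interactions with Discrete Bayesian Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies nonlinear interactions among categorical risk factors
    by comparing the combined change in outcome risk against the additive
    (no-interaction) prediction. Risk is evaluated either by exact inference
    on a discrete Bayesian network (variable elimination with an enumeration
    oracle) or directly from a table of configuration-level risks. The ratio
    of the combined delta to the sum of single-factor deltas -- the nonlinear
    effect factor -- classifies factor sets as amplifying, attenuating,
    linear, or purely synergistic. Includes maximum-likelihood conditional
    probability table estimation with optional Laplace smoothing, a seeded
    forward sampler, planted-effect synthetic network construction for
    end-to-end parameter recovery, JSON/YAML serialization, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'network.R'
    'factor.R'
    'inference.R'
    'learning.R'
    'effect.R'
    'synthetic.R'
    'schemas.R'
    'io.R'
    'cli.R'
    'show-methods.R'
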