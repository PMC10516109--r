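Package: bindgeom
Title: Binding and Generalization Tradeoffs in Linear-Nonlinear Population Codes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic theory and simulation tools for studying how neural
    populations bind feature values (such as offer value) to contexts (such as
    spatial position or presentation order) using semi-orthogonal coding
    subspaces. Provides closed-form misbinding, generalization and overall
    error rates for linear-nonlinear population codes, explicit code
    simulators with maximum-likelihood decoding, a subjective-value
    (power utility x Prelec x softmax) choice model, per-neuron encoding-model
    fits with Bayesian stacking and permutation ANOVA, subspace-correlation
    estimation with a bootstrap noise ceiling, crossnobis distance
    decomposition into linear and nonlinear components, linear decoding with
    cross-condition generalization, and generators for fully synthetic
    risky-choice sessions with controlled representational geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    pracma,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
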