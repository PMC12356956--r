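#' Validate a discrete network
#'
#' Checks every structural and probabilistic invariant of a
#' [DiscreteNetwork-class]: unique variable names, >= 2 unique levels per
#' variable, edges between declared variables with no self-loops or
#' duplicates, acyclicity, one complete CPT per variable whose parents match
#' the graph, nonnegative rows summing to 1 within `tol`.
#'
#' Violations are reported, never raised, so invalid networks can be
#' inspected.  An empty character vector means the network is valid.
#'
#' @param net a [DiscreteNetwork-class].
#' @param tol row-normalization tolerance (default `1e-9`).
#' @return character vector of violation messages (empty if valid).
#' @export
setGeneric("validateNetwork", function(net, tol = 1e-9)
  standardGeneric("validateNetwork"))

#' Topological order of a network's variables
#'
#' Kahn's algorithm with deterministic lexicographic tie-breaking: among the
#' currently parentless variables the alphabetically first is emitted next,
#' so the returned order is the lexicographically smallest valid one.
#'
#' @param net a [DiscreteNetwork-class] (CPTs not required).
#' @return character vector ordering every variable parent-before-child.
#' @export
setGeneric("topologicalOrder", function(net)
  standardGeneric("topologicalOrder"))

#' Joint probability of a full assignment
#'
#' Evaluates the chain-rule factorization
#' \eqn{P(x) = \prod_i P(x_i \mid \mathrm{parents}(x_i))} exactly.
#'
#' @param net a valid [DiscreteNetwork-class].
#' @param assignment named character vector covering every variable.
#' @return probability in \[0, 1\].
#' @export
setGeneric("jointProbability", function(net, assignment)
  standardGeneric("jointProbability"))

#' @rdname forwardSample
#' @export
setGeneric("forwardSample", function(net, n, seed, schema = "custom")
  standardGeneric("forwardSample"))

#' Risk of a single factor configuration
#'
#' The probability (or table value) of the scenario's outcome level when the
#' scenario factors are set to `config`, with the scenario context held
#' fixed.  For a network source the query runs through [vePosterior()]; for a
#' [RiskTable-class] the configuration is looked up (a missing configuration
#' is an error naming it).
#'
#' @param source a [DiscreteNetwork-class] or [RiskTable-class].
#' @param scn a [Scenario-class].
#' @param config named character vector of factor-variable levels; entries
#'   may be supplemented by the scenario context.
#' @return nonnegative numeric risk value.
#' @export
setGeneric("riskValue", function(source, scn, config)
  standardGeneric("riskValue"))

#' @rdname evaluateScenario
#' @export
setGeneric("evaluateScenario",
  function(source, scn, epsilon = 1e-12, tol = 1e-6)
    standardGeneric("evaluateScenario"))

#' Nonlinear effect factor gamma
#'
#' The gamma value carried by an [EffectReport-class] (or, for the list
#' returned by [nonlinearEffectFactor()], its `gamma` element);
#' `NA_real_` for a purely synergistic scenario.
#'
#' @param x an [EffectReport-class] or `nonlinearEffect` list.
#' @return numeric gamma or `NA_real_`.
#' @export
setGeneric("gammaValue", function(x) standardGeneric("gammaValue"))

#' Interaction classification label
#'
#' @param x an [EffectReport-class].
#' @return one of `"amplification"`, `"attenuation"`, `"linear"`,
#'   `"pure_synergy"`, `"mixed_sign"`.
#' @export
setGeneric("classification", function(x) standardGeneric("classification"))

#' Percent excess of the combined over the additive effect
#'
#' `(gamma - 1) * 100`: the percentage by which the combined effect exceeds
#' (or falls short of) the additive no-interaction prediction.  Undefined for
#' a purely synergistic scenario (gamma unbounded): that is an error.
#'
#' @param x finite numeric gamma, an [EffectReport-class], or the list
#'   returned by [nonlinearEffectFactor()].
#' @return numeric percentage.
#' @export
setGeneric("percentExcess", function(x) standardGeneric("percentExcess"))

#' Records of a sample set
#' @param x a [SampleSet-class].
#' @return data.frame of level labels.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' Provenance manifest of a sample set
#' @param x a [SampleSet-class].
#' @return list with `schema`, `n`, `seed`, `network_hash`.
#' @export
setGeneric("sampleManifest", function(x) standardGeneric("sampleManifest"))
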