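#' @import methods
NULL

#' Discrete Bayesian network
#'
#' A directed acyclic graph over named categorical variables together with one
#' conditional probability table (CPT) per variable.  The joint distribution
#' factorizes as the product of node-given-parents terms.
#'
#' Slots are structural only; semantic invariants (acyclicity, CPT
#' completeness and normalization, parent consistency) are checked by
#' [validateNetwork()], which reports violations rather than raising, so that
#' malformed networks can be inspected.
#'
#' @slot variables named list; one character vector of level labels per
#'   variable, in declaration order.  Level labels are case-sensitive opaque
#'   strings.
#' @slot edges character matrix with columns `parent`, `child` (0 rows for an
#'   edgeless network).
#' @slot cpts named list, one entry per variable (may be empty for a
#'   structure-only network).  Each entry is a list with elements `variable`,
#'   `parents` (character, in declaration order) and `prob`, a numeric matrix
#'   with one row per parent configuration (canonical row-major order over
#'   the parents: first parent varies slowest) and one column per child
#'   level.
#'
#' @seealso [discreteNetwork()], [validateNetwork()], [jointProbability()]
#' @export
setClass("DiscreteNetwork",
  representation(variables = "list", edges = "matrix", cpts = "list"))

#' Factor over a set of categorical variables
#'
#' The working object of variable elimination: a nonnegative real table over
#' the Cartesian product of its scope's levels.  Values are stored as a base
#' R array whose `dimnames` carry the scope and level labels; a factor with
#' empty scope holds a single scalar.
#'
#' @slot scope character vector of variable names (empty for a scalar).
#' @slot levels named list of level vectors, one per scope variable.
#' @slot values numeric array (or length-1 numeric when the scope is empty).
#'
#' @seealso [discreteFactor()], [factorProduct()], [factorMarginalize()],
#'   [factorReduce()]
#' @export
setClass("DiscreteFactor",
  representation(scope = "character", levels = "list", values = "ANY"))

#' Risk scenario
#'
#' Defines an interaction query: an outcome variable and level of interest, an
#' ordered set of risk factors each with a reference ("normal") level and a
#' risk (exposure) level, and optional context evidence held fixed in every
#' risk evaluation.  The baseline ("normal situation") is every factor at its
#' reference level with the context fixed.
#'
#' @slot outcome single variable name.
#' @slot outcomeLevel the outcome level whose probability is the risk.
#' @slot factors data.frame with columns `variable`, `reference`, `risk`.
#' @slot context named character vector of fixed evidence (possibly empty).
#'
#' @seealso [scenario()], [evaluateScenario()]
#' @export
setClass("Scenario",
  representation(outcome = "character", outcomeLevel = "character",
                 factors = "data.frame", context = "character"))

#' Direct risk table
#'
#' A mapping from factor configurations to nonnegative outcome risk values on
#' any consistent scale (probability, percent, ...).  Because the nonlinear
#' effect factor is a ratio of deltas it is invariant to the scale, which is
#' recorded as a note rather than normalized away.
#'
#' @slot outcome,outcomeLevel outcome variable and level the risks refer to.
#' @slot factors data.frame with columns `variable`, `reference`, `risk`.
#' @slot values data.frame with one column per factor variable plus a
#'   numeric `risk` column; one row per known configuration.
#' @slot scaleNote free-text description of the risk scale.
#'
#' @seealso [riskTable()], [evaluateScenario()], [exportRiskTable()]
#' @export
setClass("RiskTable",
  representation(outcome = "character", outcomeLevel = "character",
                 factors = "data.frame", values = "data.frame",
                 scaleNote = "character"))

#' Effect report
#'
#' Result of [evaluateScenario()]: the baseline risk, per-factor deltas, the
#' additive (sum-of-singles) and combined deltas, the nonlinear effect factor
#' gamma (NA when the scenario is purely synergistic), its classification,
#' and the percent excess (gamma - 1) * 100.
#'
#' `difference` is combined minus additive (positive when the interaction
#' amplifies risk).
#'
#' @slot scenario the evaluated [Scenario-class].
#' @slot baseline numeric baseline risk.
#' @slot deltas named numeric vector of single-factor deltas.
#' @slot additive,combined,difference numeric deltas.
#' @slot gamma numeric; `NA_real_` when `pureSynergy`.
#' @slot pureSynergy logical; additive delta is (numerically) zero while the
#'   combined delta is not, so gamma is unbounded.
#' @slot noEffect logical; both deltas numerically zero (gamma fixed at 1).
#' @slot classification one of `"amplification"`, `"attenuation"`,
#'   `"linear"`, `"pure_synergy"`, `"mixed_sign"`.
#' @slot percentExcess numeric; `NA_real_` when `pureSynergy`.
#' @slot scaleNote the source's risk-scale note.
#'
#' @seealso [evaluateScenario()], [gammaValue()], [classification()],
#'   [percentExcess()]
#' @export
setClass("EffectReport",
  representation(scenario = "Scenario", baseline = "numeric",
                 deltas = "numeric", additive = "numeric",
                 combined = "numeric", difference = "numeric",
                 gamma = "numeric", pureSynergy = "logical",
                 noEffect = "logical", classification = "character",
                 percentExcess = "numeric", scaleNote = "character"))

#' Seeded sample set
#'
#' Records forward-sampled from a network plus a provenance manifest
#' (generator network hash, sample size, seed, schema name) so any sample can
#' be regenerated byte-identically.
#'
#' @slot records data.frame of level labels, one row per observation.
#' @slot manifest list with elements `schema`, `n`, `seed`, `network_hash`.
#'
#' @seealso [forwardSample()], [records()], [sampleManifest()]
#' @export
setClass("SampleSet",
  representation(records = "data.frame", manifest = "list"))

#' Planted-effect specification
#'
#' Ground truth for a synthetic interaction network: independent binary-risk
#' root factors with given prevalences, and an outcome whose CPT is
#' constructed so the single-exposure deltas and the nonlinear effect factor
#' are known exactly.
#'
#' @slot p0 baseline outcome probability, in (0, 1).
#' @slot deltas named numeric vector of signed single-factor deltas.
#' @slot gamma target nonlinear effect factor (> 0) applied to every
#'   multi-exposure configuration.
#' @slot prevalence named numeric vector of risk-level prevalences, in (0, 1).
#' @slot outcome,outcomeLevels outcome variable name and its two levels
#'   (reference first, event second).
#' @slot riskLevels the two levels used for every factor (reference first).
#'
#' @seealso [plantSpec()], [buildPlantedNetwork()], [recoverGamma()]
#' @export
setClass("PlantSpec",
  representation(p0 = "numeric", deltas = "numeric", gamma = "numeric",
                 prevalence = "numeric", outcome = "character",
                 outcomeLevels = "character", riskLevels = "character"))
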