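## The interaction engine: baseline, single-factor, combined and additive
## deltas; the nonlinear effect factor gamma = Delta(combined)/Delta(additive);
## classification; and full scenario reports, from either a network or a
## direct risk table.

#' Construct a risk scenario
#'
#' @param outcome outcome variable name.
#' @param outcomeLevel outcome level whose probability is the risk (e.g. a
#'   fatal severity level).
#' @param factors the risk factors, as a data.frame with columns `variable`,
#'   `reference`, `risk`, or a list of `list(variable=, reference=, risk=)`.
#'   At least two factors; variables distinct; reference and risk levels must
#'   differ.
#' @param context optional named character vector of evidence held fixed in
#'   every risk query (must not involve the outcome or a factor variable).
#' @return a [Scenario-class].
#'
#' @examples
#' scenario("severity", "fatal",
#'          factors = list(
#'            list(variable = "physical_condition", reference = "normal",
#'                 risk = "dui"),
#'            list(variable = "surface", reference = "dry", risk = "snow")))
#' @export
scenario <- function(outcome, outcomeLevel, factors,
                     context = character(0)) {
  if (!isString(outcome) || !isString(outcomeLevel))
    stopf("'outcome' and 'outcomeLevel' must be single strings")
  if (is.list(factors) && !is.data.frame(factors))
    factors <- do.call(rbind, lapply(factors, function(f)
      data.frame(variable = f$variable, reference = f$reference,
                 risk = f$risk, stringsAsFactors = FALSE)))
  if (!is.data.frame(factors) ||
      !all(c("variable", "reference", "risk") %in% names(factors)))
    stopf("'factors' needs columns variable, reference, risk")
  factors <- factors[c("variable", "reference", "risk")]
  factors[] <- lapply(factors, as.character)
  rownames(factors) <- NULL
  if (nrow(factors) < 2L) stopf("a scenario needs at least 2 risk factors")
  if (anyDuplicated(factors$variable))
    stopf("scenario factors must be distinct variables")
  same <- factors$reference == factors$risk
  if (any(same))
    stopf("reference and risk level are identical for: %s",
          paste(factors$variable[same], collapse = ", "))
  context <- unlist(context) %||% character(0)
  if (length(context) == 0L) context <- character(0)
  context <- structure(as.character(context), names = names(unlist(context)))
  if (length(context) && (is.null(names(context)) || any(names(context) == "")))
    stopf("'context' must be a named character vector")
  clash <- intersect(c(outcome, factors$variable), names(context))
  if (length(clash))
    stopf("context must not fix the outcome or a factor variable: %s",
          paste(clash, collapse = ", "))
  if (outcome %in% factors$variable)
    stopf("the outcome cannot be one of the factors")
  new("Scenario", outcome = outcome, outcomeLevel = outcomeLevel,
      factors = factors, context = context)
}

#' Scenario factors
#' @param scn a [Scenario-class].
#' @return data.frame with columns `variable`, `reference`, `risk`.
#' @export
scenarioFactors <- function(scn) scn@factors

#' Construct a direct risk table
#'
#' @inheritParams scenario
#' @param values data.frame with one column per factor variable (level
#'   labels) and a numeric `risk` column, one row per configuration; or a
#'   list of `list(config = list(var = level, ...), risk = x)`.  Values must
#'   be nonnegative; at minimum the baseline, each single-risk configuration
#'   and the all-risk configuration should be present for a scenario over all
#'   factors to evaluate.
#' @param scaleNote free-text note recording the risk scale (the nonlinear
#'   effect factor is scale-invariant, so values are never renormalized).
#' @return a [RiskTable-class].
#' @export
riskTable <- function(outcome, outcomeLevel, factors, values,
                      scaleNote = "unspecified scale") {
  scn <- scenario(outcome, outcomeLevel, factors)  # reuse validation
  factors <- scn@factors
  if (is.list(values) && !is.data.frame(values)) {
    values <- do.call(rbind, lapply(values, function(v) {
      row <- as.data.frame(v$config, stringsAsFactors = FALSE)
      row$risk <- as.numeric(v$risk)
      row
    }))
  }
  if (!is.data.frame(values) || !"risk" %in% names(values))
    stopf("'values' needs factor columns and a numeric 'risk' column")
  miss <- setdiff(factors$variable, names(values))
  if (length(miss))
    stopf("'values' lacks columns for factors: %s", paste(miss, collapse = ", "))
  values <- values[c(factors$variable, "risk")]
  values$risk <- as.numeric(values$risk)
  for (j in factors$variable) values[[j]] <- as.character(values[[j]])
  rownames(values) <- NULL
  if (any(!is.finite(values$risk)) || any(values$risk < 0))
    stopf("risk values must be finite and nonnegative")
  key <- do.call(paste, c(values[factors$variable], sep = "\r"))
  if (anyDuplicated(key))
    stopf("duplicate configuration rows in risk table")
  for (i in seq_len(nrow(factors))) {
    v <- factors$variable[i]
    legal <- c(factors$reference[i], factors$risk[i])
    bad <- setdiff(unique(values[[v]]), legal)
    if (length(bad))
      stopf("unknown level(s) for '%s' in risk table: %s", v,
            paste(bad, collapse = ", "))
  }
  new("RiskTable", outcome = scn@outcome, outcomeLevel = scn@outcomeLevel,
      factors = factors, values = values, scaleNote = scaleNote)
}

## Check a scenario against a network source: variables exist, levels legal.
checkScenarioNetwork <- function(net, scn) {
  vars <- names(net@variables)
  if (!scn@outcome %in% vars)
    stopf("outcome variable '%s' not in network", scn@outcome)
  if (!scn@outcomeLevel %in% net@variables[[scn@outcome]])
    stopf("'%s' is not a level of outcome '%s'", scn@outcomeLevel,
          scn@outcome)
  for (i in seq_len(nrow(scn@factors))) {
    v <- scn@factors$variable[i]
    if (!v %in% vars) stopf("factor variable '%s' not in network", v)
    for (l in c(scn@factors$reference[i], scn@factors$risk[i]))
      if (!l %in% net@variables[[v]])
        stopf("'%s' is not a level of factor variable '%s'", l, v)
  }
  checkAssignment(net, scn@context, "context")
  invisible(TRUE)
}

#' @describeIn riskValue exact posterior query through [vePosterior()] with
#'   evidence = context plus the configuration.
setMethod("riskValue", signature(source = "DiscreteNetwork"),
  function(source, scn, config) {
    ev <- c(scn@context, unlist(config))
    post <- vePosterior(source, scn@outcome, ev)
    unname(post[[scn@outcomeLevel]])
  })

#' @describeIn riskValue table lookup; the configuration (supplemented by any
#'   context entries) must match a stored row on every table factor variable.
setMethod("riskValue", signature(source = "RiskTable"),
  function(source, scn, config) {
    config <- c(unlist(config), scn@context)
    vars <- source@factors$variable
    miss <- setdiff(vars, names(config))
    if (length(miss))
      stopf("configuration does not cover table factor(s): %s",
            paste(miss, collapse = ", "))
    hit <- rep(TRUE, nrow(source@values))
    for (v in vars) hit <- hit & source@values[[v]] == config[[v]]
    if (!any(hit))
      stopf("risk table has no configuration: %s",
            configLabel(as.list(config[vars])))
    source@values$risk[which(hit)[1L]]
  })

## Risk with factors in `active` (indices) at their risk level, all other
## scenario factors at reference.
activeRisk <- function(source, scn, active) {
  lev <- ifelse(seq_len(nrow(scn@factors)) %in% active,
                scn@factors$risk, scn@factors$reference)
  riskValue(source, scn, setNames(lev, scn@factors$variable))
}

#' Single-factor risk delta
#'
#' Risk with factor `i` at its risk level (every other factor at reference,
#' context fixed) minus the baseline risk.  May be negative for a protective
#' exposure.
#'
#' @param source a [DiscreteNetwork-class] or [RiskTable-class].
#' @param scn a [Scenario-class].
#' @param i factor index (1-based, in scenario order).
#' @return signed numeric delta.
#' @export
singleFactorDelta <- function(source, scn, i) {
  if (is(source, "DiscreteNetwork")) checkScenarioNetwork(source, scn)
  i <- assertCount(i, "'i'")
  if (i < 1L || i > nrow(scn@factors)) stopf("factor index out of range")
  activeRisk(source, scn, i) - activeRisk(source, scn, integer(0))
}

#' Additive (no-interaction) effect
#'
#' The exact sum of single-factor deltas: the linear prediction against which
#' the combined effect is compared.
#'
#' @param deltas numeric vector of signed single-factor deltas (length >= 1).
#' @return signed numeric sum.
#' @export
additiveEffect <- function(deltas) {
  deltas <- as.numeric(deltas)
  if (length(deltas) == 0L)
    stopf("no deltas given (a scenario has at least 2 factors)")
  sum(deltas)
}

#' Combined effect
#'
#' Risk with every scenario factor at its risk level (context fixed) minus
#' the baseline risk.
#'
#' @inheritParams singleFactorDelta
#' @return signed numeric delta.
#' @export
combinedEffect <- function(source, scn) {
  if (is(source, "DiscreteNetwork")) checkScenarioNetwork(source, scn)
  activeRisk(source, scn, seq_len(nrow(scn@factors))) -
    activeRisk(source, scn, integer(0))
}

#' Nonlinear effect factor
#'
#' `gamma = combined / additive`, the ratio of the combined-scenario delta to
#' the additive delta.  `gamma > 1` means the interaction amplifies risk,
#' `gamma < 1` attenuates it, `gamma = 1` is exactly linear.  When the
#' additive delta is numerically zero but the combined delta is not, gamma is
#' unbounded: the case is flagged as pure synergy and no finite value is
#' reported.  When both deltas are numerically zero, gamma is defined as 1
#' with a no-effect annotation (which keeps the reconstruction identity
#' `gamma * additive = combined` trivially true).
#'
#' @param combined,additive signed deltas on the same scale.
#' @param epsilon numerical-zero threshold on the source's scale (default
#'   `1e-12`).
#' @return list of class `"nonlinearEffect"` with elements `gamma` (numeric,
#'   `NA_real_` if pure synergy), `pureSynergy`, `noEffect` (logicals), and
#'   the input `combined` and `additive`.
#'
#' @examples
#' nonlinearEffectFactor(0.997, additiveEffect(c(0.895, 0.018)))$gamma
#' @export
nonlinearEffectFactor <- function(combined, additive, epsilon = 1e-12) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stopf("'epsilon' must be a single positive number")
  combined <- as.numeric(combined)
  additive <- as.numeric(additive)
  addZero <- abs(additive) <= epsilon
  combZero <- abs(combined) <= epsilon
  if (addZero && !combZero)
    res <- list(gamma = NA_real_, pureSynergy = TRUE, noEffect = FALSE)
  else if (addZero && combZero)
    res <- list(gamma = 1, pureSynergy = FALSE, noEffect = TRUE)
  else
    res <- list(gamma = combined / additive, pureSynergy = FALSE,
                noEffect = FALSE)
  res$combined <- combined
  res$additive <- additive
  class(res) <- "nonlinearEffect"
  res
}

#' Classify a nonlinear effect factor
#'
#' Labels an interaction: `amplification` (gamma > 1 + tol), `attenuation`
#' (gamma < 1 - tol), `linear` (|gamma - 1| <= tol), `pure_synergy` (additive
#' delta zero, combined nonzero), or `mixed_sign` (combined and additive
#' deltas of opposite sign, where the magnitude of the signed ratio is not
#' interpretable as amplification or attenuation).
#'
#' @param x a `"nonlinearEffect"` list from [nonlinearEffectFactor()], or a
#'   bare finite gamma (then only the first three labels can result).
#' @param tol classification tolerance around 1 (default `1e-6`).
#' @return single character label.
#' @export
classifyGamma <- function(x, tol = 1e-6) {
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0)
    stopf("'tol' must be a single positive number")
  if (inherits(x, "nonlinearEffect")) {
    if (x$pureSynergy) return("pure_synergy")
    if (!x$noEffect && sign(x$combined) * sign(x$additive) < 0)
      return("mixed_sign")
    g <- x$gamma
  } else g <- as.numeric(x)
  if (is.na(g)) return("pure_synergy")
  if (g > 1 + tol) "amplification"
  else if (g < 1 - tol) "attenuation"
  else "linear"
}

#' Evaluate a scenario
#'
#' Assembles the full effect report for a scenario against a network or risk
#' table: baseline risk, per-factor deltas, additive and combined deltas,
#' the nonlinear effect factor and its classification, the difference
#' (combined minus additive), and the percent excess.  When gamma is finite
#' the reconstruction identity `gamma * additive = combined` is verified
#' internally to `1e-9` (it holds by construction; the check guards the
#' implementation, not the model).
#'
#' @param source a [DiscreteNetwork-class] or [RiskTable-class].
#' @param scn a [Scenario-class] valid against the source.
#' @param epsilon numerical-zero threshold for [nonlinearEffectFactor()].
#' @param tol classification tolerance for [classifyGamma()].
#' @return an [EffectReport-class].
#'
#' @examples
#' tab <- riskTable("severity", "fatal",
#'   factors = list(
#'     list(variable = "dui", reference = "no", risk = "yes"),
#'     list(variable = "snow", reference = "no", risk = "yes")),
#'   values = data.frame(dui = c("no", "yes", "no", "yes"),
#'                       snow = c("no", "no", "yes", "yes"),
#'                       risk = c(0.259, 0.277, 0.273, 0.297)),
#'   scaleNote = "percentage-scale risk")
#' evaluateScenario(tab, scenario("severity", "fatal", scenarioFactors(tab)))
#' @name evaluateScenario
NULL

evaluateScenarioImpl <- function(source, scn, epsilon, tol) {
  n <- nrow(scn@factors)
  baseline <- activeRisk(source, scn, integer(0))
  deltas <- vapply(seq_len(n), function(i)
    activeRisk(source, scn, i) - baseline, numeric(1))
  names(deltas) <- scn@factors$variable
  additive <- additiveEffect(deltas)
  combined <- activeRisk(source, scn, seq_len(n)) - baseline
  nef <- nonlinearEffectFactor(combined, additive, epsilon)
  label <- classifyGamma(nef, tol)
  if (!nef$pureSynergy) {
    resid <- abs(nef$gamma * additive - combined)
    if (resid > 1e-9 * max(1, abs(combined)))
      stopf("internal error: reconstruction identity violated (residual %g)",
            resid)
  }
  pe <- if (nef$pureSynergy) NA_real_ else (nef$gamma - 1) * 100
  note <- if (is(source, "RiskTable")) source@scaleNote
          else "posterior probability"
  new("EffectReport", scenario = scn, baseline = baseline, deltas = deltas,
      additive = additive, combined = combined,
      difference = combined - additive,
      gamma = if (nef$pureSynergy) NA_real_ else nef$gamma,
      pureSynergy = nef$pureSynergy, noEffect = nef$noEffect,
      classification = label, percentExcess = pe, scaleNote = note)
}

#' @rdname evaluateScenario
setMethod("evaluateScenario", signature(source = "DiscreteNetwork"),
  function(source, scn, epsilon = 1e-12, tol = 1e-6) {
    checkScenarioNetwork(source, scn)
    evaluateScenarioImpl(source, scn, epsilon, tol)
  })

#' @rdname evaluateScenario
setMethod("evaluateScenario", signature(source = "RiskTable"),
  function(source, scn, epsilon = 1e-12, tol = 1e-6)
    evaluateScenarioImpl(source, scn, epsilon, tol))

#' Effect reports over factor subsets
#'
#' Evaluates one [EffectReport-class] per subset of the scenario's factors of
#' size >= 2 (or per requested subset), with the unchosen factors pinned at
#' their reference levels via the context.  Subsets are ordered by size, then
#' lexicographically by factor index, so output order is deterministic.
#'
#' @inheritParams evaluateScenario
#' @param subsets optional list of integer index vectors (each of size >= 2)
#'   selecting which subsets to evaluate; by default all `2^n - n - 1`
#'   subsets, guarded at `n <= 12`.
#' @return named list of [EffectReport-class] objects; names are the factor
#'   variables joined by `+`.
#' @export
subsetAnalysis <- function(source, scn, epsilon = 1e-12, tol = 1e-6,
                           subsets = NULL) {
  n <- nrow(scn@factors)
  if (is.null(subsets)) {
    if (n > 12L)
      stopf("%d factors give %g subsets; pass explicit 'subsets'", n, 2^n)
    subsets <- list()
    for (size in 2:n)
      subsets <- c(subsets,
                   utils::combn(n, size, simplify = FALSE))
  } else {
    subsets <- lapply(subsets, function(s) sort(as.integer(s)))
    bad <- vapply(subsets, function(s)
      length(s) < 2L || any(s < 1L | s > n) || anyDuplicated(s) > 0,
      logical(1))
    if (any(bad)) stopf("each subset must be >= 2 distinct factor indices")
  }
  out <- list()
  for (s in subsets) {
    pinned <- setdiff(seq_len(n), s)
    ctx <- c(scn@context,
             setNames(scn@factors$reference[pinned],
                      scn@factors$variable[pinned]))
    sub <- scenario(scn@outcome, scn@outcomeLevel,
                    scn@factors[s, , drop = FALSE], context = ctx)
    out[[paste(scn@factors$variable[s], collapse = "+")]] <-
      evaluateScenario(source, sub, epsilon, tol)
  }
  out
}

#' @rdname percentExcess
setMethod("percentExcess", "numeric", function(x) {
  if (length(x) != 1L || !is.finite(x))
    stopf("percent excess is undefined: gamma is not a finite number (pure synergy)")
  (x - 1) * 100
})

#' @rdname percentExcess
setMethod("percentExcess", "EffectReport", function(x) {
  if (x@pureSynergy)
    stopf("percent excess is undefined for a pure-synergy scenario")
  x@percentExcess
})

#' @rdname gammaValue
setMethod("gammaValue", "EffectReport", function(x) x@gamma)

#' @rdname classification
setMethod("classification", "EffectReport", function(x) x@classification)

#' Export a network's scenario risks as a risk table
#'
#' Queries the network posterior for every reference/risk combination of the
#' scenario factors (context fixed) and stores the results in a
#' [RiskTable-class].  Evaluating the scenario on the exported table
#' reproduces the network evaluation exactly, since both read the same
#' posterior values.
#'
#' @param net a valid [DiscreteNetwork-class].
#' @param scn a [Scenario-class].
#' @return a [RiskTable-class] with `2^n` configuration rows.
#' @export
exportRiskTable <- function(net, scn) {
  checkScenarioNetwork(net, scn)
  n <- nrow(scn@factors)
  lv <- lapply(seq_len(n), function(i)
    c(scn@factors$reference[i], scn@factors$risk[i]))
  names(lv) <- scn@factors$variable
  cfgs <- parentConfigs(lv)
  cfgs$risk <- vapply(seq_len(nrow(cfgs)), function(r)
    riskValue(net, scn, unlist(cfgs[r, scn@factors$variable, drop = FALSE])),
    numeric(1))
  riskTable(scn@outcome, scn@outcomeLevel, scn@factors, cfgs,
            scaleNote = "posterior probability")
}
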