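## Seeded synthetic data: ancestral forward sampling from any network, and
## planted-effect networks whose nonlinear effect factor is known exactly,
## so learning + effect estimation can be exercised end to end without any
## external dataset.

#' Forward (ancestral) sampling
#'
#' Draws `n` i.i.d. records from a network by sampling each variable after
#' its parents in topological order.  Sampling is wrapped in a local RNG
#' state pinned to Mersenne-Twister, so the same `(net, n, seed)` always
#' yields identical records and the caller's RNG state is untouched.
#'
#' @param net a valid [DiscreteNetwork-class].
#' @param n number of records (>= 0).
#' @param seed integer seed.
#' @param schema free-text schema name recorded in the manifest.
#' @return a [SampleSet-class]; record columns follow variable declaration
#'   order.
#' @rdname forwardSample
#' @export
setMethod("forwardSample", "DiscreteNetwork",
  function(net, n, seed, schema = "custom") {
    viol <- validateNetwork(net)
    if (length(viol))
      stopf("invalid network:\n  %s", paste(viol, collapse = "\n  "))
    n <- assertCount(n, "'n'")
    ord <- topologicalOrder(net)
    cols <- setNames(vector("list", length(ord)), ord)
    withSeed(seed, {
      for (v in ord) {
        cpt <- net@cpts[[v]]
        lv <- net@variables[[v]]
        K <- length(lv)
        if (length(cpt$parents) == 0L) {
          idx <- if (n > 0L) sample.int(K, n, replace = TRUE,
                                        prob = cpt$prob[1L, ])
                 else integer(0)
        } else {
          pdf <- as.data.frame(cols[cpt$parents], stringsAsFactors = FALSE,
                               optional = TRUE)
          names(pdf) <- cpt$parents
          cfg <- configIndex(net@variables[cpt$parents], pdf)
          idx <- integer(n)
          for (c in sort(unique(cfg))) {
            rows <- which(cfg == c)
            idx[rows] <- sample.int(K, length(rows), replace = TRUE,
                                    prob = cpt$prob[c, ])
          }
        }
        cols[[v]] <- lv[idx]
      }
    })
    rec <- as.data.frame(cols[names(net@variables)],
                         stringsAsFactors = FALSE, optional = TRUE)
    names(rec) <- names(net@variables)
    new("SampleSet", records = rec,
        manifest = list(schema = schema, n = n, seed = as.integer(seed),
                        network_hash = networkHash(net)))
  })

#' @rdname records
setMethod("records", "SampleSet", function(x) x@records)

#' @rdname sampleManifest
setMethod("sampleManifest", "SampleSet", function(x) x@manifest)

#' Construct a planted-effect specification
#'
#' Defines the ground truth for [buildPlantedNetwork()]: baseline outcome
#' probability `p0`, signed single-factor deltas, the target nonlinear effect
#' factor `gamma`, and the prevalence of each factor's risk level.
#' Feasibility (every implied outcome probability within \[0, 1\], including
#' all intermediate multi-exposure configurations) is checked up front, and
#' an infeasible specification is rejected naming the violated bound.
#'
#' @param p0 baseline outcome probability in (0, 1).
#' @param deltas numeric vector (length >= 2) of signed single-factor deltas;
#'   names become the factor variable names (default `F1`, `F2`, ...).
#' @param gamma target nonlinear effect factor (> 0) applied to the active
#'   delta sum of every configuration with two or more exposures.
#' @param prevalence risk-level prevalence per factor in (0, 1); recycled
#'   (default 0.5).
#' @param outcome,outcomeLevels outcome variable name and its two levels,
#'   reference level first.
#' @param riskLevels the two levels of every factor, reference level first.
#' @return a [PlantSpec-class].
#'
#' @examples
#' plantSpec(p0 = 0.1, deltas = c(0.05, 0.05), gamma = 1.5)
#' @export
plantSpec <- function(p0, deltas, gamma = 1, prevalence = 0.5,
                      outcome = "outcome",
                      outcomeLevels = c("none", "event"),
                      riskLevels = c("ref", "risk")) {
  deltas <- as.numeric(unlist(deltas)) |>
    stats::setNames(names(unlist(deltas)) %||% NULL)
  if (length(deltas) < 2L) stopf("need at least 2 factor deltas")
  if (is.null(names(deltas)) || any(names(deltas) == ""))
    names(deltas) <- paste0("F", seq_along(deltas))
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 >= 1)
    stopf("'p0' must be in (0, 1)")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stopf("'gamma' must be a single positive number")
  prevalence <- rep_len(as.numeric(prevalence), length(deltas))
  names(prevalence) <- names(deltas)
  if (any(prevalence <= 0 | prevalence >= 1))
    stopf("prevalences must be in (0, 1)")
  if (length(outcomeLevels) != 2L || length(riskLevels) != 2L ||
      anyDuplicated(outcomeLevels) || anyDuplicated(riskLevels))
    stopf("'outcomeLevels' and 'riskLevels' must each be 2 distinct labels")
  spec <- new("PlantSpec", p0 = p0, deltas = deltas, gamma = gamma,
              prevalence = prevalence, outcome = outcome,
              outcomeLevels = as.character(outcomeLevels),
              riskLevels = as.character(riskLevels))
  checkPlantFeasible(spec)
  spec
}

plantProb <- function(spec, active) {
  nAct <- length(active)
  if (nAct == 0L) spec@p0
  else if (nAct == 1L) spec@p0 + spec@deltas[[active]]
  else spec@p0 + spec@gamma * sum(spec@deltas[active])
}

checkPlantFeasible <- function(spec) {
  n <- length(spec@deltas)
  for (size in 0:n) for (s in utils::combn(n, size, simplify = FALSE)) {
    p <- plantProb(spec, s)
    if (p < 0 || p > 1) {
      lab <- if (length(s)) paste(names(spec@deltas)[s], collapse = ", ")
             else "(baseline)"
      stopf("infeasible specification: configuration {%s} implies outcome probability %.6g outside [0, 1]",
            lab, p)
    }
  }
  invisible(TRUE)
}

#' Build a planted-effect network
#'
#' Independent binary-risk root factors with the given prevalences, and one
#' outcome node whose CPT encodes the planted effects: the all-reference row
#' is `p0`, each single-exposure row is `p0 + d_i`, and every configuration
#' with two or more active exposures is `p0 + gamma * sum(active deltas)` --
#' the same gamma uniformly, so the ground truth is a single parameter.
#' [evaluateScenario()] on the returned network recovers `gamma` to within
#' floating point.
#'
#' @param spec a [PlantSpec-class].
#' @return a valid [DiscreteNetwork-class].
#' @export
buildPlantedNetwork <- function(spec) {
  checkPlantFeasible(spec)
  fnames <- names(spec@deltas)
  variables <- c(setNames(rep(list(spec@riskLevels), length(fnames)), fnames),
                 setNames(list(spec@outcomeLevels), spec@outcome))
  edges <- lapply(fnames, function(f) c(f, spec@outcome))
  cpts <- lapply(spec@prevalence, function(pr) c(1 - pr, pr))
  cfgs <- parentConfigs(variables[fnames])
  p <- vapply(seq_len(nrow(cfgs)), function(r)
    plantProb(spec, which(unlist(cfgs[r, ]) == spec@riskLevels[2L])),
    numeric(1))
  cpts[[spec@outcome]] <- matrix(c(1 - p, p), ncol = 2L)
  discreteNetwork(variables, edges, cpts)
}

#' Scenario implied by a planted specification
#'
#' @param spec a [PlantSpec-class].
#' @return the [Scenario-class] querying the planted outcome event over all
#'   planted factors.
#' @export
plantScenario <- function(spec) {
  scenario(spec@outcome, spec@outcomeLevels[2L],
           data.frame(variable = names(spec@deltas),
                      reference = spec@riskLevels[1L],
                      risk = spec@riskLevels[2L], stringsAsFactors = FALSE))
}

#' End-to-end gamma recovery
#'
#' The parameter-recovery harness: build the planted network, forward-sample
#' `n` records, fit CPTs from the records (known structure, optional
#' smoothing), and evaluate the planted scenario on the fitted network.  The
#' returned report's gamma is the estimate of the planted value; with small
#' `n`, unseen-configuration warnings from the fit propagate as a
#' low-confidence signal.
#'
#' @param spec a feasible [PlantSpec-class].
#' @param n sample size.
#' @param seed integer seed for the forward sampler.
#' @param alpha smoothing pseudo-count for [fitCPTs()] (default 0).
#' @return an [EffectReport-class]; `gammaValue()` gives the estimate.
#' @export
recoverGamma <- function(spec, n, seed, alpha = 0) {
  net <- buildPlantedNetwork(spec)
  ss <- forwardSample(net, n, seed, schema = "planted")
  fitted <- fitNetwork(records(ss), net, alpha)
  evaluateScenario(fitted, plantScenario(spec))
}
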