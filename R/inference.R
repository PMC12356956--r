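## Exact posterior inference over a DiscreteNetwork.
##
## Two routes with an equivalence contract: enumeratePosterior() sums the
## chain-rule joint over every completion of the evidence (the oracle), and
## vePosterior() runs variable elimination with a deterministic min-fill
## ordering.  Both return the same named probability vector within floating
## point.

checkQuery <- function(net, target, evidence) {
  viol <- validateNetwork(net)
  if (length(viol))
    stopf("invalid network:\n  %s", paste(viol, collapse = "\n  "))
  if (!isString(target) || !target %in% names(net@variables))
    stopf("unknown target variable '%s'", as.character(target)[1])
  evidence <- unlist(evidence)
  checkAssignment(net, evidence, "evidence")
  if (target %in% names(evidence))
    stopf("target '%s' must not appear in the evidence", target)
  evidence
}

#' Posterior by exhaustive enumeration
#'
#' Computes `P(target | evidence)` by summing the joint probability over all
#' completions of the evidence.  Exponential in the number of free variables;
#' intended as the independent oracle for [vePosterior()] and for small
#' networks.
#'
#' @param net a valid [DiscreteNetwork-class].
#' @param target variable to query (must not be evidenced).
#' @param evidence named character vector of observed variable = level pairs
#'   (hard evidence only; may be empty).
#' @return named numeric vector: one probability per target level, summing
#'   to 1.
#' @export
enumeratePosterior <- function(net, target, evidence = character(0)) {
  evidence <- checkQuery(net, target, evidence)
  free <- setdiff(names(net@variables), names(evidence))
  card <- lengths(net@variables[free])
  if (prod(card) > 5e6)
    stopf("enumeration over %g states is too large; use vePosterior()",
          prod(card))
  grid <- expand.grid(net@variables[free], KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  for (v in names(evidence)) grid[[v]] <- evidence[[v]]
  p <- jointVector(net, grid)
  lv <- net@variables[[target]]
  post <- vapply(lv, function(l) sum(p[grid[[target]] == l]), numeric(1))
  tot <- sum(post)
  if (!is.finite(tot) || tot <= 0)
    stopf("impossible evidence: P(%s) = 0", configLabel(as.list(evidence)))
  post / tot
}

## Min-fill elimination variable: among `elim`, the variable whose removal
## adds the fewest new pairwise connections to the interaction graph induced
## by the current factor scopes; ties broken lexicographically.
minFillPick <- function(scopes, elim) {
  adjacent <- function(a, b)
    any(vapply(scopes, function(s) a %in% s && b %in% s, logical(1)))
  best <- NULL
  bestFill <- Inf
  for (v in sort(elim)) {
    nbrs <- sort(unique(unlist(scopes[vapply(scopes, function(s) v %in% s,
                                             logical(1))])))
    nbrs <- setdiff(nbrs, v)
    fill <- 0L
    if (length(nbrs) > 1L) {
      for (i in seq_len(length(nbrs) - 1L))
        for (j in seq(i + 1L, length(nbrs)))
          if (!adjacent(nbrs[i], nbrs[j])) fill <- fill + 1L
    }
    if (fill < bestFill) { bestFill <- fill; best <- v }
  }
  best
}

#' Posterior by variable elimination
#'
#' Exact `P(target | evidence)` via factor algebra: every CPT is reduced by
#' the evidence, the remaining variables are eliminated in min-fill order
#' (lexicographic tie-break, so the computation is deterministic), and the
#' result is normalized.  Agrees with [enumeratePosterior()] within floating
#' point on every input.
#'
#' @inheritParams enumeratePosterior
#' @return named numeric vector: one probability per target level, summing
#'   to 1.
#'
#' @examples
#' net <- discreteNetwork(
#'   variables = list(A = c("0", "1"), B = c("0", "1")),
#'   edges = list(c("A", "B")),
#'   cpts = list(A = c(0.5, 0.5),
#'               B = rbind(c(0.8, 0.2), c(0.2, 0.8))))
#' vePosterior(net, "A", c(B = "1"))  # P(A=1 | B=1) = 0.8
#' @export
vePosterior <- function(net, target, evidence = character(0)) {
  evidence <- checkQuery(net, target, evidence)
  constant <- 1
  factors <- list()
  for (v in names(net@variables)) {
    f <- factorReduce(cptFactor(net, v), evidence)
    if (length(f@scope) == 0L) constant <- constant * as.numeric(f@values)
    else factors[[length(factors) + 1L]] <- f
  }
  elim <- setdiff(names(net@variables), c(target, names(evidence)))
  while (length(elim)) {
    scopes <- lapply(factors, function(f) f@scope)
    v <- minFillPick(scopes, elim)
    elim <- setdiff(elim, v)
    hit <- vapply(factors, function(f) v %in% f@scope, logical(1))
    if (!any(hit)) next  # variable already absent from every scope
    prod <- Reduce(factorProduct, factors[hit])
    marg <- factorMarginalize(prod, v)
    factors <- factors[!hit]
    if (length(marg@scope) == 0L) constant <- constant * as.numeric(marg@values)
    else factors[[length(factors) + 1L]] <- marg
  }
  lv <- net@variables[[target]]
  post <- setNames(rep(constant, length(lv)), lv)
  if (length(factors)) {
    final <- Reduce(factorProduct, factors)
    # remaining scope can only be the target
    vals <- as.numeric(final@values)[match(lv, final@levels[[target]])]
    post <- post * vals
  }
  tot <- sum(post)
  if (!is.finite(tot) || tot <= 0)
    stopf("impossible evidence: P(%s) = 0", configLabel(as.list(evidence)))
  post / tot
}
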