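#' Construct a factor
#'
#' @param scope character vector of variable names (empty for a scalar
#'   factor).
#' @param levels named list of level vectors, one per scope variable.
#' @param values numeric array in native (column-major) layout over the
#'   scope, i.e. the first scope variable varies fastest; a single number
#'   when the scope is empty.  All entries must be nonnegative.
#' @return a [DiscreteFactor-class].
#' @export
discreteFactor <- function(scope, levels, values) {
  scope <- as.character(scope)
  if (length(scope) == 0L) {
    if (length(values) != 1L) stopf("scalar factor needs a single value")
    return(new("DiscreteFactor", scope = character(0), levels = list(),
               values = as.numeric(values)))
  }
  if (!is.list(levels) || !setequal(names(levels), scope))
    stopf("'levels' must be a named list covering the scope")
  levels <- levels[scope]
  card <- lengths(levels)
  values <- as.numeric(values)
  if (length(values) != prod(card))
    stopf("value table incomplete: %d values for %d cells", length(values),
          prod(card))
  if (any(!is.finite(values)) || any(values < 0))
    stopf("factor values must be finite and nonnegative")
  arr <- array(values, dim = card, dimnames = levels)
  new("DiscreteFactor", scope = scope, levels = levels, values = arr)
}

factorCard <- function(f) lengths(f@levels)

## CPT of variable v as a factor over (v, parents).
cptFactor <- function(net, v) {
  cpt <- net@cpts[[v]]
  pars <- cpt$parents
  scope <- c(v, pars)
  levels <- net@variables[scope]
  card <- lengths(levels)
  N <- prod(card)
  idx <- arrayInd(seq_len(N), card)
  cfg <- rowMajorIndex(idx[, -1L, drop = FALSE], card[-1L])
  discreteFactor(scope, levels, cpt$prob[cbind(cfg, idx[, 1L])])
}

#' Factor product
#'
#' Pointwise product over the union scope (standard factor algebra of
#' variable elimination).  Scalar factors act as constants.
#'
#' @param f1,f2 [DiscreteFactor-class] objects with consistent levels on any
#'   shared variables.
#' @return a [DiscreteFactor-class] over the union of the scopes.
#' @export
factorProduct <- function(f1, f2) {
  for (v in intersect(f1@scope, f2@scope))
    if (!identical(f1@levels[[v]], f2@levels[[v]]))
      stopf("inconsistent levels for shared variable '%s'", v)
  if (length(f1@scope) == 0L)
    return(new("DiscreteFactor", scope = f2@scope, levels = f2@levels,
               values = f2@values * as.numeric(f1@values)))
  if (length(f2@scope) == 0L)
    return(new("DiscreteFactor", scope = f1@scope, levels = f1@levels,
               values = f1@values * as.numeric(f2@values)))
  scope <- union(f1@scope, f2@scope)
  levels <- c(f1@levels, f2@levels[setdiff(f2@scope, f1@scope)])[scope]
  card <- lengths(levels)
  N <- prod(card)
  idx <- arrayInd(seq_len(N), card)
  v1 <- f1@values[linearIndex(factorCard(f1),
                              idx[, match(f1@scope, scope), drop = FALSE])]
  v2 <- f2@values[linearIndex(factorCard(f2),
                              idx[, match(f2@scope, scope), drop = FALSE])]
  new("DiscreteFactor", scope = scope, levels = levels,
      values = array(v1 * v2, dim = card, dimnames = levels))
}

#' Marginalize a variable out of a factor
#'
#' Sums the factor over all levels of `var`, removing it from the scope.
#'
#' @param f a [DiscreteFactor-class].
#' @param var variable name in the factor's scope.
#' @return a [DiscreteFactor-class] over the remaining scope (scalar if none
#'   remains).
#' @export
factorMarginalize <- function(f, var) {
  if (!var %in% f@scope) stopf("'%s' is not in the factor scope", var)
  keep <- which(f@scope != var)
  if (length(keep) == 0L)
    return(new("DiscreteFactor", scope = character(0), levels = list(),
               values = sum(f@values)))
  vals <- apply(f@values, keep, sum)
  levels <- f@levels[keep]
  new("DiscreteFactor", scope = f@scope[keep], levels = levels,
      values = array(vals, dim = lengths(levels), dimnames = levels))
}

#' Reduce a factor by hard evidence
#'
#' Slices the factor to the rows consistent with `evidence`, dropping the
#' evidenced variables from the scope.  Variables in the evidence but not in
#' the scope are ignored.
#'
#' @param f a [DiscreteFactor-class].
#' @param evidence named character vector of variable = level.
#' @return a [DiscreteFactor-class] over the un-evidenced scope.
#' @export
factorReduce <- function(f, evidence) {
  evidence <- unlist(evidence)
  hit <- intersect(names(evidence), f@scope)
  if (length(hit) == 0L) return(f)
  idx <- vector("list", length(f@scope))
  for (j in seq_along(f@scope)) {
    v <- f@scope[j]
    if (v %in% hit) {
      i <- match(evidence[[v]], f@levels[[v]])
      if (is.na(i))
        stopf("'%s' is not a level of variable '%s'", evidence[[v]], v)
      idx[[j]] <- i
    } else idx[[j]] <- seq_along(f@levels[[v]])
  }
  args <- c(list(f@values), idx, list(drop = FALSE))
  vals <- do.call(`[`, args)
  keep <- which(!f@scope %in% hit)
  if (length(keep) == 0L)
    return(new("DiscreteFactor", scope = character(0), levels = list(),
               values = as.numeric(vals)))
  levels <- f@levels[keep]
  new("DiscreteFactor", scope = f@scope[keep], levels = levels,
      values = array(as.numeric(vals), dim = lengths(levels),
                     dimnames = levels))
}

#' Factor values
#'
#' The value table of a factor as a named array (or a single number for a
#' scalar factor).
#'
#' @param f a [DiscreteFactor-class].
#' @export
factorValues <- function(f) f@values
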