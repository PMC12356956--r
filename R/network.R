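#' Construct a discrete Bayesian network
#'
#' @param variables named list: one character vector of level labels per
#'   variable (>= 2 unique labels each).  Declaration order is preserved and
#'   fixes the canonical parent order of every CPT.
#' @param edges directed edges, as a list of `c(parent, child)` pairs or a
#'   two-column character matrix; `NULL` for an edgeless graph.
#' @param cpts named list of conditional probability tables, or `NULL` for a
#'   structure-only network (e.g. as input to [fitNetwork()]).  Each entry is
#'   either a numeric vector over the child levels (root variable) or a
#'   matrix with one row per parent configuration in canonical row-major
#'   order (first declared parent slowest) and one column per child level.
#'   Columns may be named; unnamed columns are taken in level order.
#' @param check validate and stop on violations (default `TRUE`; always
#'   skipped for structure-only networks, whose tables are absent by design).
#' @return a [DiscreteNetwork-class].
#'
#' @examples
#' net <- discreteNetwork(
#'   variables = list(A = c("no", "yes"), B = c("no", "yes")),
#'   edges = list(c("A", "B")),
#'   cpts = list(A = c(0.7, 0.3),
#'               B = rbind(c(0.9, 0.1), c(0.2, 0.8))))
#' jointProbability(net, c(A = "yes", B = "yes"))  # 0.3 * 0.8
#' @export
discreteNetwork <- function(variables, edges = NULL, cpts = NULL,
                            check = TRUE) {
  if (!is.list(variables) || is.null(names(variables)) ||
      any(names(variables) == ""))
    stopf("'variables' must be a named list of level vectors")
  variables <- lapply(variables, as.character)

  if (is.null(edges)) {
    em <- matrix(character(0), 0L, 2L)
  } else if (is.matrix(edges)) {
    em <- matrix(as.character(edges), ncol = 2L)
  } else if (is.list(edges)) {
    bad <- !vapply(edges, function(e) length(e) == 2L, logical(1))
    if (any(bad)) stopf("each edge must be a (parent, child) pair")
    em <- do.call(rbind, lapply(edges, as.character))
    if (is.null(em)) em <- matrix(character(0), 0L, 2L)
  } else stopf("'edges' must be a list of pairs or a two-column matrix")
  colnames(em) <- c("parent", "child")

  net <- new("DiscreteNetwork", variables = variables, edges = em,
             cpts = list())
  if (!is.null(cpts)) {
    if (is.null(names(cpts))) stopf("'cpts' must be a named list")
    built <- list()
    for (v in names(cpts)) {
      if (!v %in% names(variables))
        stopf("cpt given for undeclared variable '%s'", v)
      built[[v]] <- buildCPT(net, v, cpts[[v]])
    }
    net@cpts <- built
    if (check) {
      viol <- validateNetwork(net)
      if (length(viol))
        stopf("invalid network:\n  %s", paste(viol, collapse = "\n  "))
    }
  }
  net
}

## Normalize a user-supplied CPT (vector or config x level matrix) into the
## internal canonical form for variable v, with parents taken from the graph.
buildCPT <- function(net, v, prob) {
  pars <- graphParents(net, v)
  lv <- net@variables[[v]]
  K <- length(lv)
  nCfg <- prod(lengths(net@variables[pars]))
  if (is.null(dim(prob))) prob <- matrix(as.numeric(prob), nrow = 1L)
  prob <- as.matrix(prob)
  if (!is.null(colnames(prob))) {
    miss <- setdiff(lv, colnames(prob))
    if (length(miss))
      stopf("cpt for '%s' lacks columns for levels: %s", v,
            paste(miss, collapse = ", "))
    prob <- prob[, lv, drop = FALSE]
  }
  if (ncol(prob) != K)
    stopf("cpt for '%s': %d columns but %d levels", v, ncol(prob), K)
  if (nrow(prob) != nCfg)
    stopf("cpt for '%s': %d rows but %d parent configurations", v,
          nrow(prob), nCfg)
  dimnames(prob) <- list(NULL, lv)
  storage.mode(prob) <- "double"
  list(variable = v, parents = pars, prob = prob)
}

#' Graph parents of a variable
#'
#' Parents of `v` in a network's edge set, order-normalized to variable
#' declaration order (the canonical CPT parent order).
#'
#' @param net a [DiscreteNetwork-class].
#' @param v variable name.
#' @return character vector of parent names (possibly empty).
#' @export
networkParents <- function(net, v) graphParents(net, v)

graphParents <- function(net, v) {
  p <- unique(net@edges[net@edges[, 2L] == v, 1L])
  names(net@variables)[names(net@variables) %in% p]
}

#' Network accessors
#'
#' `networkVariables` returns the named list of level vectors;
#' `networkEdges` the two-column edge matrix; `networkCPT` one variable's
#' conditional probability table (list with `variable`, `parents`, `prob`).
#'
#' @param net a [DiscreteNetwork-class].
#' @param v variable name (for `networkCPT`).
#' @name network-accessors
#' @export
networkVariables <- function(net) net@variables

#' @rdname network-accessors
#' @export
networkEdges <- function(net) net@edges

#' @rdname network-accessors
#' @export
networkCPT <- function(net, v) {
  if (!v %in% names(net@cpts)) stopf("no cpt for variable '%s'", v)
  net@cpts[[v]]
}

#' @rdname validateNetwork
setMethod("validateNetwork", "DiscreteNetwork", function(net, tol = 1e-9) {
  viol <- character(0)
  say <- function(...) viol[[length(viol) + 1L]] <<- sprintf(...)

  vars <- names(net@variables)
  if (anyDuplicated(vars))
    say("duplicate variable names: %s",
        paste(unique(vars[duplicated(vars)]), collapse = ", "))
  for (v in vars) {
    lv <- net@variables[[v]]
    if (length(lv) < 2L)
      say("variable '%s' has fewer than 2 levels", v)
    if (anyDuplicated(lv))
      say("variable '%s' has duplicate levels: %s", v,
          paste(unique(lv[duplicated(lv)]), collapse = ", "))
  }

  em <- net@edges
  if (nrow(em)) {
    undecl <- setdiff(unique(c(em)), vars)
    if (length(undecl))
      say("edges reference undeclared variables: %s",
          paste(undecl, collapse = ", "))
    self <- em[, 1L] == em[, 2L]
    if (any(self))
      say("self-loop on: %s", paste(unique(em[self, 1L]), collapse = ", "))
    key <- paste(em[, 1L], em[, 2L], sep = "\r")
    if (anyDuplicated(key))
      say("duplicate edges: %s",
          paste(unique(gsub("\r", "->", key[duplicated(key)])),
                collapse = ", "))
  }
  cyc <- tryCatch({ topologicalOrder(net); NULL },
                  error = function(e) conditionMessage(e))
  if (!is.null(cyc)) say("%s", cyc)

  if (length(net@cpts) == 0L) {
    say("no conditional probability tables (structure-only network)")
    return(viol)
  }
  miss <- setdiff(vars, names(net@cpts))
  if (length(miss))
    say("missing cpt for: %s", paste(miss, collapse = ", "))
  extra <- setdiff(names(net@cpts), vars)
  if (length(extra))
    say("cpt for undeclared variable: %s", paste(extra, collapse = ", "))

  for (v in intersect(vars, names(net@cpts))) {
    cpt <- net@cpts[[v]]
    pars <- graphParents(net, v)
    if (!identical(cpt$parents, pars)) {
      say("cpt for '%s': parents (%s) do not match graph parents (%s)", v,
          paste(cpt$parents, collapse = ", "), paste(pars, collapse = ", "))
      next
    }
    lv <- net@variables[[v]]
    nCfg <- prod(lengths(net@variables[pars]))
    pm <- cpt$prob
    if (!is.matrix(pm) || nrow(pm) != nCfg || ncol(pm) != length(lv)) {
      say("cpt for '%s': expected %d x %d probability matrix", v, nCfg,
          length(lv))
      next
    }
    cfgs <- parentConfigs(net@variables[pars])
    for (r in seq_len(nCfg)) {
      row <- pm[r, ]
      lab <- if (length(pars)) configLabel(cfgs[r, , drop = FALSE])
             else "(no parents)"
      if (any(!is.finite(row)))
        say("cpt for '%s': row %d (%s) has non-finite entries", v, r, lab)
      else {
        if (any(row < 0))
          say("cpt for '%s': row %d (%s) has negative probabilities", v, r,
              lab)
        if (abs(sum(row) - 1) > tol)
          say("cpt for '%s': row %d (%s) sums to %.12g, not 1 (normalization)",
              v, r, lab, sum(row))
      }
    }
  }
  viol
})

#' @rdname topologicalOrder
setMethod("topologicalOrder", "DiscreteNetwork", function(net) {
  vars <- sort(names(net@variables))
  em <- net@edges
  indeg <- setNames(integer(length(vars)), vars)
  if (nrow(em)) {
    tab <- table(em[, 2L])
    indeg[names(tab)] <- as.integer(tab)
  }
  out <- character(0)
  avail <- vars[indeg == 0L]  # already sorted
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    out <- c(out, v)
    if (nrow(em)) {
      ch <- em[em[, 1L] == v, 2L]
      for (c in ch) {
        indeg[c] <- indeg[c] - 1L
        if (indeg[c] == 0L) avail <- sort(c(avail, c))
      }
    }
  }
  if (length(out) < length(vars))
    stopf("cycle detected among variables: %s",
          paste(sort(setdiff(vars, out)), collapse = ", "))
  out
})

## Chain-rule joint probability for every row of a full-assignment
## data.frame; vectorized over rows.  Shared by jointProbability() and the
## enumeration oracle.
jointVector <- function(net, df) {
  p <- rep(1, nrow(df))
  for (v in names(net@variables)) {
    cpt <- net@cpts[[v]]
    cfg <- configIndex(net@variables[cpt$parents], df)
    ci <- match(df[[v]], net@variables[[v]])
    p <- p * cpt$prob[cbind(cfg, ci)]
  }
  p
}

checkAssignment <- function(net, assignment, what = "assignment") {
  if (length(assignment) && (is.null(names(assignment)) ||
                             any(names(assignment) == "")))
    stopf("%s must be a named character vector", what)
  unknown <- setdiff(names(assignment), names(net@variables))
  if (length(unknown))
    stopf("%s names unknown variables: %s", what,
          paste(unknown, collapse = ", "))
  if (anyDuplicated(names(assignment)))
    stopf("%s assigns a variable twice", what)
  for (v in names(assignment))
    if (!assignment[[v]] %in% net@variables[[v]])
      stopf("'%s' is not a level of variable '%s'", assignment[[v]], v)
  invisible(TRUE)
}

#' @rdname jointProbability
setMethod("jointProbability", "DiscreteNetwork", function(net, assignment) {
  assignment <- unlist(assignment)
  checkAssignment(net, assignment)
  missing <- setdiff(names(net@variables), names(assignment))
  if (length(missing))
    stopf("assignment is partial; missing variables: %s",
          paste(missing, collapse = ", "))
  df <- as.data.frame(as.list(assignment), stringsAsFactors = FALSE)
  jointVector(net, df)
})

#' Content hash of a network
#'
#' MD5 digest of the canonical JSON serialization (full numeric precision),
#' used in sample-set manifests so records can be traced to the exact
#' generating network.
#'
#' @param net a [DiscreteNetwork-class].
#' @return 32-character hex string.
#' @export
networkHash <- function(net) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeNetwork(net, tf)
  unname(tools::md5sum(tf))
}
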