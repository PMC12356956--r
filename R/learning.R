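## Maximum-likelihood CPT estimation from categorical records, with optional
## Laplace smoothing.  Missing cells (NA or "") are handled complete-case per
## table: a record is dropped only from the tables whose variable or parents
## it leaves unobserved, and the per-table exclusion count is logged.

#' Tabulate sufficient statistics for CPT estimation
#'
#' Counts child-level occurrences per parent configuration for every variable
#' of a network structure.  Rows with a missing value (`NA` or `""`) in the
#' variable or any of its parents are excluded from that variable's table
#' only; the number excluded is attached as attribute `"excluded"` and logged
#' via [message()].
#'
#' @param rec a data.frame of level labels (or a [SampleSet-class]); columns
#'   must cover every network variable.
#' @param structure a [DiscreteNetwork-class]; only its variables, levels and
#'   edges are used, so a structure-only network is accepted.
#' @return named list of count tables: each a list with `variable`,
#'   `parents`, and integer matrix `counts` (parent configurations in
#'   canonical row-major order x child levels), with attribute `"excluded"`.
#' @export
tabulateCounts <- function(rec, structure) {
  if (is(rec, "SampleSet")) rec <- records(rec)
  if (!is.data.frame(rec)) stopf("'rec' must be a data.frame or SampleSet")
  vars <- names(structure@variables)
  missingCols <- setdiff(vars, names(rec))
  if (length(missingCols))
    stopf("records lack columns for variables: %s",
          paste(missingCols, collapse = ", "))
  rec <- rec[vars]
  for (v in vars) {
    col <- as.character(rec[[v]])
    col[!is.na(col) & col == ""] <- NA_character_
    bad <- which(!is.na(col) & !col %in% structure@variables[[v]])
    if (length(bad))
      stopf("illegal level '%s' for variable '%s' at record row %d",
            col[bad[1L]], v, bad[1L])
    rec[[v]] <- col
  }
  out <- list()
  for (v in vars) {
    pars <- graphParents(structure, v)
    lv <- structure@variables[[v]]
    K <- length(lv)
    nCfg <- prod(lengths(structure@variables[pars]))
    sub <- rec[c(v, pars)]
    ok <- stats::complete.cases(sub)
    excluded <- sum(!ok)
    sub <- sub[ok, , drop = FALSE]
    cfg <- configIndex(structure@variables[pars], sub)
    ci <- match(sub[[v]], lv)
    counts <- matrix(tabulate((cfg - 1L) * K + ci, nbins = nCfg * K),
                     nrow = nCfg, ncol = K, byrow = TRUE,
                     dimnames = list(NULL, lv))
    if (excluded > 0)
      message(sprintf("tabulateCounts: %d record(s) excluded for '%s' (missing value in variable or parents)",
                      excluded, v))
    tab <- list(variable = v, parents = pars, counts = counts)
    attr(tab, "excluded") <- excluded
    out[[v]] <- tab
  }
  out
}

#' Estimate CPTs from count tables
#'
#' `P(level | config) = (count + alpha) / (total + alpha * K)` with `K` the
#' number of child levels: maximum likelihood at `alpha = 0`, Laplace
#' smoothing for `alpha > 0` (`alpha = 1` is a sensible default for sparse
#' data, so unseen levels retain mass).  A parent configuration with zero
#' total and `alpha = 0` yields a uniform row with a warning rather than an
#' error, so sparse categorical data never blocks a fit.
#'
#' @param counts list of count tables from [tabulateCounts()].
#' @param alpha nonnegative smoothing pseudo-count (default 0).
#' @return named list of probability matrices (one per variable, canonical
#'   row order).
#' @export
fitCPTs <- function(counts, alpha = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stopf("'alpha' must be a single nonnegative number")
  out <- list()
  for (tab in counts) {
    cm <- tab$counts
    K <- ncol(cm)
    tot <- rowSums(cm) + alpha * K
    prob <- (cm + alpha) / tot
    zero <- tot == 0
    if (any(zero)) {
      warning(sprintf("fitCPTs: %d unseen parent configuration(s) for '%s'; using uniform rows",
                      sum(zero), tab$variable), call. = FALSE)
      prob[zero, ] <- 1 / K
    }
    out[[tab$variable]] <- prob
  }
  out
}

#' Fit a network from records
#'
#' Convenience wrapper: [tabulateCounts()] then [fitCPTs()], returning a full
#' [DiscreteNetwork-class] with the given structure and fitted tables.
#'
#' @inheritParams tabulateCounts
#' @inheritParams fitCPTs
#' @return a valid [DiscreteNetwork-class].
#' @export
fitNetwork <- function(rec, structure, alpha = 0) {
  cpts <- fitCPTs(tabulateCounts(rec, structure), alpha)
  discreteNetwork(structure@variables, structure@edges, cpts)
}
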