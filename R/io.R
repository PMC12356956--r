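## On-disk formats.  JSON is the canonical dialect (written with canonical
## key and row order at full numeric precision, so networks round-trip
## bit-identically); YAML is accepted on read as a superset syntax.

readSpecFile <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  parsed <- tryCatch({
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
      yaml::read_yaml(path)
    else jsonlite::fromJSON(path, simplifyVector = FALSE)
  }, error = function(e)
    stopf("parse error in '%s': %s", path, conditionMessage(e)))
  if (!is.list(parsed)) stopf("parse error in '%s': not a mapping", path)
  parsed
}

# digits = I(17): full double precision, so serialized networks round-trip
# bit-identically
writeJSON <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")

## ---- networks ----

networkToList <- function(net) {
  vars <- lapply(names(net@variables), function(v)
    list(name = v, levels = as.list(net@variables[[v]])))
  edges <- lapply(seq_len(nrow(net@edges)), function(i)
    as.list(unname(net@edges[i, ])))
  cpts <- lapply(names(net@variables), function(v) {
    cpt <- net@cpts[[v]]
    if (is.null(cpt)) return(NULL)
    cfgs <- parentConfigs(net@variables[cpt$parents])
    rows <- lapply(seq_len(nrow(cpt$prob)), function(r) {
      given <- if (length(cpt$parents)) as.list(cfgs[r, , drop = FALSE])
               else stats::setNames(list(), character(0))
      list(given = given,
           p = as.list(stats::setNames(cpt$prob[r, ],
                                       net@variables[[v]])))
    })
    list(variable = v, parents = as.list(cpt$parents), rows = rows)
  })
  list(type = "network", variables = vars, edges = edges,
       cpts = Filter(Negate(is.null), cpts))
}

#' Write a network to JSON
#'
#' Canonical serialization: declaration-ordered variables, CPT rows in
#' canonical row-major parent-configuration order, full numeric precision.
#' `readNetwork(writeNetwork(net))` reproduces `net` bit-identically.
#'
#' @param net a [DiscreteNetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path) {
  writeJSON(networkToList(net), path)
  invisible(path)
}

#' Read a network from JSON or YAML
#'
#' Accepts the network spec dialect: top-level `variables` (list of
#' `{name, levels}`), `edges` (list of `[parent, child]` pairs) and optional
#' `cpts` (list of `{variable, parents, rows: [{given, p}]}`).  CPT rows may
#' appear in any order and parents in any order; both are normalized to
#' canonical form on load.
#'
#' @param path input file (`.json`, `.yaml` or `.yml`).
#' @param renormalize divide each CPT row by its sum on load (default
#'   `FALSE`: rows are never silently renormalized; a row off by more than
#'   the tolerance is a validation failure instead).
#' @param check stop if [validateNetwork()] reports violations (default
#'   `TRUE`).  With `check = FALSE` the (possibly invalid or structure-only)
#'   network is returned for inspection.
#' @return a [DiscreteNetwork-class].
#' @export
readNetwork <- function(path, renormalize = FALSE, check = TRUE) {
  spec <- readSpecFile(path)
  if (is.null(spec$variables)) stopf("parse error in '%s': no 'variables'", path)
  variables <- list()
  for (v in spec$variables) {
    if (is.null(v$name) || is.null(v$levels))
      stopf("parse error in '%s': variable entry needs 'name' and 'levels'",
            path)
    variables[[v$name]] <- as.character(unlist(v$levels))
  }
  edges <- lapply(spec$edges, function(e) as.character(unlist(e)))
  net <- discreteNetwork(variables, edges)
  if (length(spec$cpts %||% list())) {
    cpts <- list()
    for (entry in spec$cpts) {
      v <- entry$variable
      if (is.null(v) || !v %in% names(variables))
        stopf("parse error in '%s': cpt for unknown variable", path)
      pars <- graphParents(net, v)
      declared <- as.character(unlist(entry$parents))
      if (!setequal(declared, pars))
        stopf("cpt for '%s': parents (%s) do not match graph parents (%s)",
              v, paste(declared, collapse = ", "),
              paste(pars, collapse = ", "))
      lv <- variables[[v]]
      nCfg <- prod(lengths(variables[pars]))
      prob <- matrix(NA_real_, nCfg, length(lv),
                     dimnames = list(NULL, lv))
      for (row in entry$rows) {
        given <- lapply(row$given, as.character)
        miss <- setdiff(pars, names(given))
        if (length(miss))
          stopf("cpt row for '%s' lacks parent(s): %s", v,
                paste(miss, collapse = ", "))
        r <- configIndex(variables[pars],
                         as.data.frame(given[pars],
                                       stringsAsFactors = FALSE,
                                       optional = TRUE) |>
                           stats::setNames(pars))
        if (length(pars) == 0L) r <- 1L
        if (is.na(r))
          stopf("cpt row for '%s' has an illegal parent level (%s)", v,
                configLabel(given))
        p <- row$p
        missLv <- setdiff(lv, names(p))
        if (length(missLv))
          stopf("cpt row for '%s' lacks probabilities for level(s): %s", v,
                paste(missLv, collapse = ", "))
        prob[r, ] <- as.numeric(unlist(p[lv]))
      }
      if (anyNA(prob))
        stopf("cpt for '%s' is incomplete: %d of %d parent configurations given",
              v, sum(stats::complete.cases(prob)), nCfg)
      if (renormalize) prob <- prob / rowSums(prob)
      cpts[[v]] <- prob
    }
    net <- discreteNetwork(variables, edges, cpts, check = FALSE)
  }
  if (check && length(net@cpts)) {
    viol <- validateNetwork(net)
    if (length(viol))
      stopf("invalid network in '%s':\n  %s", path,
            paste(viol, collapse = "\n  "))
  }
  net
}

## ---- risk tables, scenarios, reports ----

factorsToList <- function(factors)
  lapply(seq_len(nrow(factors)), function(i)
    list(variable = factors$variable[i], reference = factors$reference[i],
         risk = factors$risk[i]))

factorsFromList <- function(lst)
  do.call(rbind, lapply(lst, function(f)
    data.frame(variable = as.character(f$variable),
               reference = as.character(f$reference),
               risk = as.character(f$risk), stringsAsFactors = FALSE)))

#' Write a risk table to JSON
#' @param tab a [RiskTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRiskTable <- function(tab, path) {
  vals <- lapply(seq_len(nrow(tab@values)), function(r)
    list(config = as.list(tab@values[r, tab@factors$variable, drop = FALSE]),
         risk = tab@values$risk[r]))
  writeJSON(list(type = "risk_table", outcome = tab@outcome,
                 outcome_level = tab@outcomeLevel,
                 scale_note = tab@scaleNote,
                 factors = factorsToList(tab@factors), values = vals),
            path)
  invisible(path)
}

#' Read a risk table from JSON or YAML
#'
#' Dialect: `{outcome, outcome_level, scale_note, factors: [{variable,
#' reference, risk}], values: [{config: {var: level, ...}, risk: number}]}`.
#'
#' @param path input file.
#' @return a [RiskTable-class].
#' @export
readRiskTable <- function(path) {
  spec <- readSpecFile(path)
  for (k in c("outcome", "outcome_level", "factors", "values"))
    if (is.null(spec[[k]])) stopf("parse error in '%s': no '%s'", path, k)
  riskTable(as.character(spec$outcome), as.character(spec$outcome_level),
            factorsFromList(spec$factors), spec$values,
            scaleNote = as.character(spec$scale_note %||%
                                     "unspecified scale"))
}

#' Write a scenario to JSON
#' @param scn a [Scenario-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeScenario <- function(scn, path) {
  writeJSON(list(type = "scenario", outcome = scn@outcome,
                 outcome_level = scn@outcomeLevel,
                 factors = factorsToList(scn@factors),
                 context = as.list(scn@context)),
            path)
  invisible(path)
}

#' Read a scenario from JSON or YAML
#'
#' Dialect: `{outcome, outcome_level, factors: [{variable, reference,
#' risk}], context: {var: level, ...}}`.
#'
#' @param path input file.
#' @return a [Scenario-class].
#' @export
readScenario <- function(path) {
  spec <- readSpecFile(path)
  for (k in c("outcome", "outcome_level", "factors"))
    if (is.null(spec[[k]])) stopf("parse error in '%s': no '%s'", path, k)
  ctx <- unlist(lapply(spec$context %||% list(), as.character))
  scenario(as.character(spec$outcome), as.character(spec$outcome_level),
           factorsFromList(spec$factors),
           context = ctx %||% character(0))
}

reportToList <- function(rep) {
  list(type = "effect_report",
       outcome = rep@scenario@outcome,
       outcome_level = rep@scenario@outcomeLevel,
       factors = factorsToList(rep@scenario@factors),
       context = as.list(rep@scenario@context),
       baseline = rep@baseline,
       deltas = as.list(rep@deltas),
       additive = rep@additive,
       combined = rep@combined,
       difference = rep@difference,
       gamma = if (rep@pureSynergy) NULL else rep@gamma,
       pure_synergy = rep@pureSynergy,
       no_effect = rep@noEffect,
       classification = rep@classification,
       percent_excess = if (rep@pureSynergy) NULL else rep@percentExcess,
       scale_note = rep@scaleNote)
}

#' Write an effect report to JSON
#' @param rep an [EffectReport-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(rep, path) {
  writeJSON(reportToList(rep), path)
  invisible(path)
}

#' Format an effect report as an aligned text table
#'
#' One row per quantity (baseline, each single-factor delta, additive and
#' combined effects, their difference, gamma, percent excess), mirroring the
#' layout used for multifactor worked examples.
#'
#' @param rep an [EffectReport-class].
#' @return character vector of lines.
#' @export
formatReport <- function(rep) {
  num <- function(x) formatC(x, digits = 6, format = "fg")
  rows <- list(
    c("baseline risk", num(rep@baseline)))
  for (i in seq_along(rep@deltas))
    rows <- c(rows, list(c(sprintf("delta %s (%s -> %s)",
                                   names(rep@deltas)[i],
                                   rep@scenario@factors$reference[i],
                                   rep@scenario@factors$risk[i]),
                           num(rep@deltas[i]))))
  rows <- c(rows, list(
    c("added factor effect (a)", num(rep@additive)),
    c("combined factor effect (b)", num(rep@combined)),
    c("difference (b) - (a)", num(rep@difference)),
    c("nonlinear effect factor",
      if (rep@pureSynergy) "pure synergy (unbounded)" else num(rep@gamma)),
    c("percent excess",
      if (rep@pureSynergy) "-" else paste0(num(rep@percentExcess), "%")),
    c("classification", rep@classification),
    c("scale", rep@scaleNote)))
  lhs <- vapply(rows, `[`, character(1), 1L)
  rhs <- vapply(rows, `[`, character(1), 2L)
  sprintf("%-*s  %s", max(nchar(lhs)), lhs, rhs)
}

## ---- records ----

#' Read categorical records from CSV
#'
#' Header row of variable names; cells are level labels; an empty cell is a
#' missing value.
#'
#' @param path CSV file path.
#' @return data.frame of character columns with `""` mapped to `NA`.
#' @export
readRecords <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  rec <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  rec[] <- lapply(rec, function(col) {
    col[col == ""] <- NA_character_
    col
  })
  rec
}

#' Write a sample set to CSV plus manifest JSON
#'
#' @param ss a [SampleSet-class].
#' @param recordsPath output CSV path (missing values written as empty
#'   cells).
#' @param manifestPath optional manifest JSON path.
#' @return `recordsPath`, invisibly.
#' @export
writeSampleSet <- function(ss, recordsPath, manifestPath = NULL) {
  utils::write.csv(records(ss), recordsPath, row.names = FALSE, na = "")
  if (!is.null(manifestPath)) writeJSON(sampleManifest(ss), manifestPath)
  invisible(recordsPath)
}

#' Read a planted-effect specification from JSON or YAML
#'
#' Dialect: `{p0, deltas: {factor: delta, ...}, gamma, prevalence: number or
#' {factor: p, ...}}` with optional `outcome`, `outcome_levels`,
#' `risk_levels`.
#'
#' @param path input file.
#' @return a [PlantSpec-class].
#' @export
readPlantSpec <- function(path) {
  spec <- readSpecFile(path)
  for (k in c("p0", "deltas")) if (is.null(spec[[k]]))
    stopf("parse error in '%s': no '%s'", path, k)
  deltas <- unlist(spec$deltas)
  prev <- spec$prevalence %||% 0.5
  if (is.list(prev)) prev <- unlist(prev)[names(deltas)]
  plantSpec(p0 = as.numeric(spec$p0), deltas = deltas,
            gamma = as.numeric(spec$gamma %||% 1),
            prevalence = as.numeric(prev),
            outcome = as.character(spec$outcome %||% "outcome"),
            outcomeLevels = as.character(unlist(
              spec$outcome_levels %||% c("none", "event"))),
            riskLevels = as.character(unlist(
              spec$risk_levels %||% c("ref", "risk"))))
}
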