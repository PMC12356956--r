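setMethod("show", "DiscreteNetwork", function(object) {
  nv <- length(object@variables)
  cat(sprintf("DiscreteNetwork: %d variable%s, %d edge%s, %s\n", nv,
              if (nv == 1) "" else "s", nrow(object@edges),
              if (nrow(object@edges) == 1) "" else "s",
              if (length(object@cpts)) "with CPTs" else "structure only"))
  for (v in names(object@variables)) {
    pars <- graphParents(object, v)
    cat(sprintf("  %s {%s}%s\n", v,
                paste(object@variables[[v]], collapse = ", "),
                if (length(pars)) paste0(" | ", paste(pars, collapse = ", "))
                else ""))
  }
  invisible(NULL)
})

setMethod("show", "DiscreteFactor", function(object) {
  if (length(object@scope) == 0L)
    cat("DiscreteFactor: scalar =", as.numeric(object@values), "\n")
  else {
    cat("DiscreteFactor over", paste(object@scope, collapse = ", "), "\n")
    print(object@values)
  }
  invisible(NULL)
})

setMethod("show", "Scenario", function(object) {
  cat(sprintf("Scenario: P(%s = %s)\n", object@outcome,
              object@outcomeLevel))
  for (i in seq_len(nrow(object@factors)))
    cat(sprintf("  factor %s: %s -> %s\n", object@factors$variable[i],
                object@factors$reference[i], object@factors$risk[i]))
  if (length(object@context))
    cat("  context:", configLabel(as.list(object@context)), "\n")
  invisible(NULL)
})

setMethod("show", "RiskTable", function(object) {
  cat(sprintf("RiskTable: %s = %s over %d factor(s), %d configuration(s) [%s]\n",
              object@outcome, object@outcomeLevel, nrow(object@factors),
              nrow(object@values), object@scaleNote))
  print(object@values)
  invisible(NULL)
})

setMethod("show", "EffectReport", function(object) {
  cat("EffectReport\n")
  cat(paste0("  ", formatReport(object)), sep = "\n")
  invisible(NULL)
})

setMethod("show", "SampleSet", function(object) {
  m <- object@manifest
  cat(sprintf("SampleSet: %d record(s), schema '%s', seed %d, network %s\n",
              nrow(object@records), m$schema, m$seed,
              substr(m$network_hash, 1, 8)))
  invisible(NULL)
})

setMethod("show", "PlantSpec", function(object) {
  cat(sprintf("PlantSpec: p0 = %g, gamma = %g\n", object@p0, object@gamma))
  for (f in names(object@deltas))
    cat(sprintf("  %s: delta %+g, prevalence %g\n", f, object@deltas[[f]],
                object@prevalence[[f]]))
  invisible(NULL)
})
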