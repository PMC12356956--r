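# In-code fixtures shared across test files.  All randomness is drawn under
# an explicit set.seed() at the call site.

# Random DAG + random strictly-positive CPTs over nVars variables with 2 to
# maxLevels levels each.
randomNetwork <- function(nVars, maxLevels = 3, edgeProb = 0.4) {
  vars <- paste0("V", seq_len(nVars))
  levels <- lapply(vars, function(v)
    paste0("l", seq_len(sample(2:maxLevels, 1))))
  names(levels) <- vars
  ord <- sample(vars)
  edges <- list()
  if (nVars > 1) {
    for (i in 2:nVars) for (j in seq_len(i - 1))
      if (runif(1) < edgeProb) edges <- c(edges, list(c(ord[j], ord[i])))
  }
  skeleton <- discreteNetwork(levels, edges)
  cpts <- lapply(vars, function(v) {
    pars <- networkParents(skeleton, v)
    nCfg <- prod(lengths(levels[pars]))
    K <- length(levels[[v]])
    m <- matrix(rgamma(nCfg * K, 1) + 0.05, nCfg, K)
    m / rowSums(m)
  })
  names(cpts) <- vars
  discreteNetwork(levels, edges, cpts)
}

# All full assignments of a network as a data.frame of level labels.
allAssignments <- function(net)
  expand.grid(networkVariables(net), KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)

# Independent brute-force joint probability of one full assignment: walks
# the CPT lists directly, multiplying matrix entries looked up by hand
# (no shared code with jointProbability/jointVector).
bruteJoint <- function(net, assignment) {
  levels <- networkVariables(net)
  p <- 1
  for (v in names(levels)) {
    cpt <- networkCPT(net, v)
    row <- 1L
    for (par in cpt$parents) {
      K <- length(levels[[par]])
      row <- (row - 1L) * K + match(assignment[[par]], levels[[par]])
    }
    p <- p * cpt$prob[row, match(assignment[[v]], levels[[v]])]
  }
  unname(p)
}

# Independent posterior oracle built on bruteJoint only.
brutePosterior <- function(net, target, evidence = character(0)) {
  grid <- allAssignments(net)
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) keep <- keep & grid[[v]] == evidence[[v]]
  grid <- grid[keep, , drop = FALSE]
  p <- vapply(seq_len(nrow(grid)), function(r)
    bruteJoint(net, as.list(grid[r, , drop = FALSE])), numeric(1))
  lv <- networkVariables(net)[[target]]
  post <- vapply(lv, function(l) sum(p[grid[[target]] == l]), numeric(1))
  post / sum(post)
}

# Two-node chain used in several files: P(A=1)=0.5, P(B=1|A=1)=0.8,
# P(B=1|A=0)=0.2.
chainAB <- function()
  discreteNetwork(
    variables = list(A = c("0", "1"), B = c("0", "1")),
    edges = list(c("A", "B")),
    cpts = list(A = c(0.5, 0.5),
                B = rbind(c(0.8, 0.2), c(0.2, 0.8))))

# The worked-example fixtures shipped with the package.
fixturePath <- function(name)
  system.file("extdata", name, package = "riskbn", mustWork = TRUE)
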