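test_that("a well-formed network validates with an empty report", {
  expect_length(validateNetwork(chainAB()), 0)
})

test_that("validation reports cycles, bad rows and missing tables without raising", {
  cyc <- discreteNetwork(list(A = c("0", "1"), B = c("0", "1")),
                         edges = list(c("A", "B"), c("B", "A")))
  expect_match(paste(validateNetwork(cyc), collapse = " "), "cycle")

  bad <- discreteNetwork(list(A = c("0", "1"), B = c("0", "1")),
                         edges = list(c("A", "B")),
                         cpts = list(A = c(0.5, 0.5),
                                     B = rbind(c(0.7, 0.2), c(0.2, 0.8))),
                         check = FALSE)
  viol <- validateNetwork(bad)
  expect_match(paste(viol, collapse = " "), "normalization")
  expect_match(paste(viol, collapse = " "), "row 1 \\(A=0\\)")

  structOnly <- discreteNetwork(list(A = c("0", "1"), B = c("0", "1")))
  expect_match(paste(validateNetwork(structOnly), collapse = " "),
               "structure-only")

  dup <- discreteNetwork(list(A = c("0", "1"), B = c("0", "1")),
                         edges = list(c("A", "B"), c("A", "B")))
  expect_match(paste(validateNetwork(dup), collapse = " "), "duplicate edges")
})

test_that("topological order is parent-before-child with lexicographic ties", {
  chain <- discreteNetwork(list(A = c("0", "1"),
                                B = c("0", "1"), C = c("0", "1")),
                           edges = list(c("A", "B"), c("B", "C")))
  expect_identical(topologicalOrder(chain), c("A", "B", "C"))

  noEdges <- discreteNetwork(list(B = c("0", "1"), A = c("0", "1")))
  expect_identical(topologicalOrder(noEdges), c("A", "B"))

  # diamond: the valid orders are ABCD and ACBD; lexicographically first wins
  diamond <- discreteNetwork(
    list(A = c("0", "1"), B = c("0", "1"), C = c("0", "1"), D = c("0", "1")),
    edges = list(c("A", "B"), c("A", "C"), c("B", "D"), c("C", "D")))
  expect_identical(topologicalOrder(diamond), c("A", "B", "C", "D"))

  cyc <- discreteNetwork(list(A = c("0", "1"), B = c("0", "1")),
                         edges = list(c("A", "B"), c("B", "A")))
  expect_error(topologicalOrder(cyc), "cycle.*A.*B")
})

test_that("jointProbability is the chain-rule product", {
  ind <- discreteNetwork(list(A = c("0", "1"), B = c("0", "1")),
                         cpts = list(A = c(0.5, 0.5), B = c(0.5, 0.5)))
  expect_equal(jointProbability(ind, c(A = "1", B = "0")), 0.25)

  chain <- discreteNetwork(list(A = c("0", "1"), B = c("0", "1")),
                           edges = list(c("A", "B")),
                           cpts = list(A = c(0.7, 0.3),
                                       B = rbind(c(0.9, 0.1), c(0.1, 0.9))))
  expect_equal(jointProbability(chain, c(A = "1", B = "1")), 0.3 * 0.9)

  expect_error(jointProbability(chain, c(A = "1")), "missing variables: B")
})

test_that("jointProbability matches an independent brute-force product on a diamond", {
  set.seed(404)
  net <- discreteNetwork(
    list(A = c("a1", "a2"), B = c("b1", "b2", "b3"), C = c("c1", "c2")),
    edges = list(c("A", "B"), c("A", "C")),
    cpts = list(A = c(0.4, 0.6),
                B = rbind(c(0.2, 0.3, 0.5), c(0.6, 0.3, 0.1)),
                C = rbind(c(0.25, 0.75), c(0.9, 0.1))))
  grid <- allAssignments(net)
  for (r in seq_len(nrow(grid))) {
    a <- unlist(grid[r, , drop = FALSE])
    expect_equal(jointProbability(net, a),
                 bruteJoint(net, as.list(a)), tolerance = 1e-12)
  }
})

test_that("the joint distribution sums to 1 on random networks", {
  set.seed(101)
  for (rep in 1:20) {
    net <- randomNetwork(sample(2:5, 1))
    grid <- allAssignments(net)
    tot <- sum(vapply(seq_len(nrow(grid)), function(r)
      jointProbability(net, unlist(grid[r, , drop = FALSE])), numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-9)
  }
})

test_that("jointProbability is invariant to variable declaration order", {
  net1 <- discreteNetwork(list(A = c("0", "1"), B = c("0", "1")),
                          edges = list(c("A", "B")),
                          cpts = list(A = c(0.7, 0.3),
                                      B = rbind(c(0.9, 0.1), c(0.1, 0.9))))
  net2 <- discreteNetwork(list(B = c("0", "1"), A = c("0", "1")),
                          edges = list(c("A", "B")),
                          cpts = list(A = c(0.7, 0.3),
                                      B = rbind(c(0.9, 0.1), c(0.1, 0.9))))
  grid <- allAssignments(net1)
  for (r in seq_len(nrow(grid))) {
    a <- unlist(grid[r, , drop = FALSE])
    expect_equal(jointProbability(net1, a), jointProbability(net2, a))
  }
})

test_that("networks produced by the synthetic module all validate", {
  expect_length(validateNetwork(crashSchema()), 0)
  expect_length(validateNetwork(healthSchema()), 0)
  spec <- plantSpec(0.1, c(0.05, -0.02, 0.1), gamma = 1.3)
  expect_length(validateNetwork(buildPlantedNetwork(spec)), 0)
  set.seed(77)
  for (rep in 1:10) expect_length(validateNetwork(randomNetwork(4)), 0)
})
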