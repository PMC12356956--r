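# The shipped worked-example fixtures: a two-factor delta-encoded table
# (impaired driving x snowy road) and a three-factor fatal-risk table
# (impaired driving x snowy road x no seatbelt, percentage-type scale).

threeFactorTable <- function() readRiskTable(fixturePath("scenario3_table3.json"))
threeFactorScenario <- function() readScenario(fixturePath("scenario3.json"))

test_that("single-factor deltas are risk-minus-baseline and may be zero", {
  tab <- threeFactorTable()
  scn <- threeFactorScenario()
  expect_equal(singleFactorDelta(tab, scn, 1), 0.277 - 0.259)  # impaired only
  expect_equal(singleFactorDelta(tab, scn, 3), 4.793 - 0.259)  # no belt only

  flat <- riskTable("y", "bad",
    factors = list(list(variable = "f1", reference = "a", risk = "b"),
                   list(variable = "f2", reference = "a", risk = "b")),
    values = data.frame(f1 = c("a", "b", "a", "b"),
                        f2 = c("a", "a", "b", "b"),
                        risk = c(0.3, 0.3, 0.4, 0.5)))
  scn2 <- scenario("y", "bad", scenarioFactors(flat))
  expect_equal(singleFactorDelta(flat, scn2, 1), 0)

  expect_error(singleFactorDelta(tab, scn, 4), "out of range")
})

test_that("a missing risk-table configuration is an error naming it", {
  tab <- threeFactorTable()
  scn <- threeFactorScenario()
  # dui + no-belt with dry road is not among the fixture's configurations
  expect_error(
    riskValue(tab, scn, c(physical_condition = "dui", surface = "dry",
                          safety_equipment = "none")),
    "no configuration.*physical_condition=dui.*surface=dry")
})

test_that("additiveEffect is the exact sum of deltas", {
  expect_equal(additiveEffect(c(0.018, 0.014, 4.534)), 4.566)
  expect_equal(additiveEffect(c(0.895, 0.018)), 0.913)
  expect_equal(additiveEffect(c(0.02, -0.02)), 0)
  expect_error(additiveEffect(numeric(0)), "at least 2 factors")
})

test_that("combinedEffect is all-risk minus baseline", {
  tab <- threeFactorTable()
  expect_equal(combinedEffect(tab, threeFactorScenario()), 5.193 - 0.259)
  withBelt <- readScenario(fixturePath("scenario_withbelt.json"))
  expect_equal(combinedEffect(tab, withBelt), 0.297 - 0.259)
})

test_that("the nonlinear effect factor reproduces the worked ratios", {
  g1 <- nonlinearEffectFactor(0.997, 0.913)
  expect_equal(g1$gamma, 1.092, tolerance = 1e-3)
  g3 <- nonlinearEffectFactor(4.934, 4.566)
  expect_equal(g3$gamma, 1.081, tolerance = 1e-3)

  ps <- nonlinearEffectFactor(0.05, 0)
  expect_true(ps$pureSynergy)
  expect_true(is.na(ps$gamma))

  ne <- nonlinearEffectFactor(0, 0)
  expect_true(ne$noEffect)
  expect_equal(ne$gamma, 1)
})

test_that("classification covers amplification, attenuation, linear, synergy, mixed sign", {
  expect_identical(classifyGamma(1.081), "amplification")
  expect_identical(classifyGamma(1.0), "linear")
  expect_identical(classifyGamma(0.8), "attenuation")
  expect_identical(classifyGamma(nonlinearEffectFactor(0.05, 0)),
                   "pure_synergy")
  expect_identical(classifyGamma(nonlinearEffectFactor(-0.1, 0.2)),
                   "mixed_sign")
  expect_identical(classifyGamma(1 + 1e-9), "linear")
})

test_that("percentExcess is (gamma - 1) * 100 and undefined for pure synergy", {
  expect_equal(percentExcess(1.092), 9.2, tolerance = 1e-12)
  expect_equal(percentExcess(1.0), 0)
  # exact arithmetic from the rounded deltas gives 8.06; the reference
  # value rounds to 8.1
  expect_equal(percentExcess(4.934 / 4.566), 8.1, tolerance = 0.05)
  expect_error(percentExcess(NA_real_), "pure synergy")
})

test_that("evaluateScenario assembles the three-factor worked report", {
  rep <- evaluateScenario(threeFactorTable(), threeFactorScenario())
  expect_equal(rep@baseline, 0.259)
  expect_equal(unname(rep@deltas), c(0.018, 0.014, 4.534))
  expect_equal(rep@additive, 4.566)
  expect_equal(rep@combined, 4.934)
  expect_equal(rep@difference, 0.368)
  expect_equal(gammaValue(rep), 1.081, tolerance = 1e-3)
  expect_identical(classification(rep), "amplification")
  expect_equal(gammaValue(rep) * rep@additive, rep@combined,
               tolerance = 1e-9)
})

test_that("evaluateScenario reproduces the two-factor with-belt report", {
  rep <- evaluateScenario(threeFactorTable(),
                          readScenario(fixturePath("scenario_withbelt.json")))
  expect_equal(rep@additive, 0.032)
  expect_equal(rep@combined, 0.038)
  expect_equal(percentExcess(rep), 18.7, tolerance = 0.1)
})

test_that("an outcome independent of the factors yields a linear no-effect report", {
  net <- discreteNetwork(
    list(F1 = c("a", "b"), F2 = c("a", "b"), Y = c("0", "1")),
    cpts = list(F1 = c(0.5, 0.5), F2 = c(0.5, 0.5), Y = c(0.8, 0.2)))
  scn <- scenario("Y", "1",
                  list(list(variable = "F1", reference = "a", risk = "b"),
                       list(variable = "F2", reference = "a", risk = "b")))
  rep <- evaluateScenario(net, scn)
  expect_equal(unname(rep@deltas), c(0, 0))
  expect_true(rep@noEffect)
  expect_identical(classification(rep), "linear")
})

test_that("subsetAnalysis enumerates size >= 2 subsets deterministically", {
  spec <- plantSpec(0.1, c(0.04, 0.05, 0.06), gamma = 1.4)
  net <- buildPlantedNetwork(spec)
  scn <- plantScenario(spec)
  subs <- subsetAnalysis(net, scn)
  expect_length(subs, 4)  # {1,2}, {1,3}, {2,3}, {1,2,3}
  expect_identical(names(subs),
                   c("F1+F2", "F1+F3", "F2+F3", "F1+F2+F3"))
  # unchosen factor pinned at reference: the pairwise subset keeps gamma*
  expect_equal(gammaValue(subs[["F1+F2"]]), 1.4, tolerance = 1e-9)

  two <- subsetAnalysis(net, scenario(scn@outcome, scn@outcomeLevel,
                                      scn@factors[1:2, ]))
  expect_length(two, 1)

  # explicit subsets: the with-belt pair present in the three-factor table
  subs2 <- subsetAnalysis(threeFactorTable(), threeFactorScenario(),
                          subsets = list(c(1, 2)))
  expect_equal(subs2[[1]]@additive, 0.032)
  expect_equal(subs2[[1]]@combined, 0.038)
})

test_that("gamma, classification and percent excess are scale invariant", {
  tab <- threeFactorTable()
  scn <- threeFactorScenario()
  base <- evaluateScenario(tab, scn)
  for (c in c(0.01, 7.3, 1000)) {
    scaled <- tab
    scaled@values$risk <- scaled@values$risk * c
    rep <- evaluateScenario(scaled, scn)
    expect_equal(gammaValue(rep), gammaValue(base), tolerance = 1e-12)
    expect_identical(classification(rep), classification(base))
    expect_equal(percentExcess(rep), percentExcess(base), tolerance = 1e-9)
    expect_equal(rep@additive, base@additive * c, tolerance = 1e-9)
  }
})

test_that("the reconstruction identity holds on every finite-gamma report", {
  set.seed(88)
  for (rep_i in 1:20) {
    n <- sample(2:4, 1)
    # draws kept inside the feasible region: |gamma * sum(d)| <= 0.3 < p0
    spec <- plantSpec(runif(1, 0.35, 0.5),
                      runif(n, 0.01, 0.05) * sample(c(-1, 1), n, TRUE),
                      gamma = runif(1, 0.3, 1.5))
    r <- evaluateScenario(buildPlantedNetwork(spec), plantScenario(spec))
    if (!r@pureSynergy)
      expect_equal(gammaValue(r) * r@additive, r@combined, tolerance = 1e-9)
  }
})

test_that("an exactly additive network yields gamma = 1", {
  spec <- plantSpec(0.15, c(0.05, 0.03, 0.07), gamma = 1)
  r <- evaluateScenario(buildPlantedNetwork(spec), plantScenario(spec))
  expect_equal(gammaValue(r), 1, tolerance = 1e-9)
  expect_identical(classification(r), "linear")
})

test_that("network and exported risk table give identical reports", {
  net <- crashSchema()
  scn <- scenario("severity", "fatal",
    list(list(variable = "physical_condition", reference = "normal",
              risk = "dui"),
         list(variable = "surface", reference = "dry", risk = "snow"),
         list(variable = "safety_equipment", reference = "belt",
              risk = "none")))
  tab <- exportRiskTable(net, scn)
  repNet <- evaluateScenario(net, scn)
  repTab <- evaluateScenario(tab, scn)
  expect_identical(repNet@baseline, repTab@baseline)
  expect_identical(repNet@deltas, repTab@deltas)
  expect_identical(repNet@combined, repTab@combined)
  expect_identical(gammaValue(repNet), gammaValue(repTab))
})

test_that("permuting the factor list only relabels the report", {
  tab <- threeFactorTable()
  scn <- threeFactorScenario()
  perm <- scenario(scn@outcome, scn@outcomeLevel,
                   scn@factors[c(3, 1, 2), ])
  r1 <- evaluateScenario(tab, scn)
  r2 <- evaluateScenario(tab, perm)
  expect_equal(r2@additive, r1@additive)
  expect_equal(r2@combined, r1@combined)
  expect_equal(gammaValue(r2), gammaValue(r1))
  expect_equal(sort(names(r2@deltas)), sort(names(r1@deltas)))
  expect_equal(r2@deltas[names(r1@deltas)], r1@deltas)
})

test_that("scenario construction rejects degenerate inputs", {
  expect_error(scenario("y", "1", list(
    list(variable = "f", reference = "a", risk = "a"),
    list(variable = "g", reference = "a", risk = "b"))),
    "identical")
  expect_error(scenario("y", "1", list(
    list(variable = "f", reference = "a", risk = "b"))),
    "at least 2")
  expect_error(scenario("y", "1", list(
    list(variable = "y", reference = "a", risk = "b"),
    list(variable = "g", reference = "a", risk = "b"))),
    "outcome")
})
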