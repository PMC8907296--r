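test_that("confounder subset enumeration is complete", {
  expect_length(enumerateConfounderModels(c("dna", "vcn", "ps", "sd")), 15)
  expect_length(enumerateConfounderModels("sd"), 1)
  expect_length(enumerateConfounderModels(c("a", "b", "c")), 7)
  expect_error(enumerateConfounderModels(character()), "at least one")
  subs <- enumerateConfounderModels(c("a", "b"))
  expect_setequal(vapply(subs, paste, "", collapse = "+"), c("a", "b", "a+b"))
})

test_that("information criteria follow their printed formulas", {
  et <- makeSingleConfounderTable(n = 40, sigma = 0.1, seed = 30)
  fit <- fitScs(et, scsModel(list(scsTerm("xvar", 1))))
  n <- 40
  p <- faceDim(fit)
  rss <- sum(residuals(fit)^2)
  logL <- -n / 2 * (log(2 * pi * rss / n) + 1)
  aic <- -2 * logL + 2 * p
  expect_equal(aicc(fit), aic + 2 * p * (p + 1) / (n - p))
  expect_equal(bic(fit), aic + p * (log(n) - 2))
  # n = e^2 makes BIC = AIC (log n = 2): check the identity algebraically
  expect_equal(bic(fit) - (-2 * logL + p * log(n)), 0)
})

test_that("BIC weights are stable, normalized and shift invariant", {
  expect_equal(bicWeights(c(10, 10, 10)), rep(1 / 3, 3))
  w <- bicWeights(c(0, 2 * log(9)))
  expect_equal(w, c(0.9, 0.1))
  b <- c(123.4, 120.1, 150.9)
  expect_equal(bicWeights(b), bicWeights(b + 777))
  expect_equal(sum(bicWeights(c(1e6, 1e6 + 1, 1e6 + 2))), 1)
})

test_that("model averaging embeds, weights and marginalizes correctly", {
  et <- simulateEntropyDataset(
    n = 120,
    confounders = list(
      dna_ng = list(range = c(5, 100),
                    effect = function(x) 1.0 * x / (20 + x)),
      sd = list(range = c(600, 50000), effect = function(x) 0 * x)),
    sigma = 0.1, seed = 33)
  model <- scsModel(list(scsTerm("dna_ng", 1), scsTerm("sd", 1)))
  avg <- modelAverage(et, model)
  expect_equal(sum(avg@weights), 1, tolerance = 1e-12)
  expect_equal(nrow(avg@models), 3)
  # inclusion probability = sum of weights of subsets containing the term
  for (v in c("dna_ng", "sd")) {
    inSub <- grepl(v, avg@models$subset)
    expect_equal(unname(avg@inclusionProbs[v]), sum(avg@weights[inSub]))
    expect_gte(avg@inclusionProbs[[v]], 0)
    expect_lte(avg@inclusionProbs[[v]], 1)
  }
  # the active confounder dominates
  expect_gt(avg@inclusionProbs[["dna_ng"]], avg@inclusionProbs[["sd"]])
  # averaged coefficients live in the full layout, absent blocks at zero
  full <- fitScs(et, model)
  expect_setequal(names(avg@betaFma), names(coef(full)))
})

test_that("a single candidate model collapses the average onto its fit", {
  et <- makeSingleConfounderTable(n = 50, sigma = 0.1, seed = 34)
  et$xvar2 <- NULL
  model <- scsModel(list(scsTerm("xvar", 1)))
  avg <- modelAverage(et, model)
  expect_equal(avg@weights, 1)
  fit <- avg@fits[[1]]
  expect_equal(avg@betaFma[names(coef(fit))], coef(fit), tolerance = 1e-12)
  expect_equal(unname(avg@inclusionProbs), 1)
  expect_equal(rescaleEntropies(avg), rescaleEntropies(fit), tolerance = 1e-12)
})
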