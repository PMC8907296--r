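test_that("transduction counts follow the Poisson MOI model", {
  expect_equal(simulateTransduction(100, 0, seed = 1), rep(0L, 100))
  n <- 1e5
  m <- 1.3
  cnt <- simulateTransduction(n, m, seed = 2)
  p0 <- mean(cnt == 0)
  se0 <- sqrt(exp(-m) * (1 - exp(-m)) / n)
  expect_lt(abs(p0 - exp(-m)), 3 * se0)
  seMean <- sqrt(m / n)
  expect_lt(abs(mean(cnt) - m), 3 * seMean)
})

test_that("IS samples are seed-deterministic and saturate at the pool entropy", {
  pool <- simulateClonePool(nCells = 800, moi = 1, seed = 3)
  s1 <- simulateISSample(pool, 20, 5000, seed = 4)
  s2 <- simulateISSample(pool, 20, 5000, seed = 4)
  expect_identical(s1, s2)
  expect_equal(sum(s1$abundances), 5000)
  expect_true(all(names(s1$abundances) %in% names(pool$freq)))
  # huge aliquot and depth: observed entropy converges to the truth
  big <- simulateISSample(pool, 1e4, 1e6, seed = 5)
  expect_lt(abs(shannonEntropy(big$abundances) - pool$entropy), 0.01)
})

test_that("observed entropy is nondecreasing in depth on average", {
  pool <- simulateClonePool(nCells = 600, moi = 0.5, seed = 6)
  depths <- c(100, 400, 1600, 6400)
  set.seed(7)
  meanH <- vapply(depths, function(d)
    mean(vapply(1:25, function(r)
      shannonEntropy(simulateISSample(pool, 10, d)$abundances), 0)), 0)
  expect_true(all(diff(meanH) > 0))
})

test_that("the entropy-table generator honours its own model", {
  # no confounders, no noise: constant h = exp(beta0)
  et0 <- simulateEntropyDataset(n = 10, confounders = list(), beta0 = 1.7,
                                sigma = 0, seed = 8)
  expect_equal(et0$h, rep(exp(1.7), 10))
  et <- simulateEntropyDataset(n = 50, seed = 9)
  truth <- attr(et, "truth")
  expect_named(truth$effects, c("dna_ng", "vcn", "sd"))
  # generated effects are monotone and concave on a grid by construction
  for (nm in names(truth$effects)) {
    g <- seq(min(et[[nm]]), max(et[[nm]]), length.out = 500)
    v <- truth$effects[[nm]](g)
    expect_gte(min(diff(v)), 0)
    expect_lte(max(diff(v, differences = 2)), 1e-12)
  }
  expect_identical(simulateEntropyDataset(n = 20, seed = 10),
                   simulateEntropyDataset(n = 20, seed = 10))
  expect_false(identical(simulateEntropyDataset(n = 20, seed = 10)$h,
                         simulateEntropyDataset(n = 20, seed = 11)$h))
})

test_that("in-vitro assay produces a confounded ISAbundanceExperiment", {
  ise <- simulateInVitroAssay(nCells = 500, seed = 12)
  expect_s4_class(ise, "ISAbundanceExperiment")
  cd <- as.data.frame(SummarizedExperiment::colData(ise))
  expect_equal(nrow(cd), 27)  # 3 moi x 3 dna x 3 replicates
  expect_equal(length(unique(cd$vcn)), 3)  # one VCN per transduction arm
  expect_equal(length(unique(cd$dna_ng)), 3)
  cnt <- SummarizedExperiment::assay(ise, "counts")
  expect_equal(unname(colSums(cnt)), as.numeric(cd$sd))
  # entropy increases with the confounders: positive observed correlation
  et <- buildEntropyTable(ise)
  expect_gt(spearmanTest(et$h, et$sd)$rho, 0)
})

test_that("mouse design has shrinking pools and eight decay blocks", {
  mt <- simulateMouseDesign(seed = 13)
  byPool <- split(mt, paste(mt$pool, mt$lineage))
  expect_true(all(vapply(byPool, function(d)
    all(diff(d$ps[order(d$time)]) <= 0), TRUE)))
  truth <- attr(mt, "truth")
  expect_length(truth$decays, 8)  # 4 lineages x 2 vectors
  # genotoxic-arm decay is steeper except in the B compartment
  tEnd <- 6
  for (l in c("MNC", "T", "Myeloid"))
    expect_lt(truth$decays[[paste0("decay.", l, ".LTR")]](tEnd),
              truth$decays[[paste0("decay.", l, ".PGK")]](tEnd))
})

test_that("fitted decay splines recover the genotoxicity ordering", {
  model <- scsModel(
    list(scsTerm("dna_ng", 2), scsTerm("vcn", 2), scsTerm("ps", 1),
         scsTerm("sd", 2)),
    factors = scsDecayFactors())
  hit <- 0
  nSeeds <- 10
  for (s in seq_len(nSeeds)) {
    mt <- simulateMouseDesign(seed = 100 + s)
    fit <- fitScs(mt, model)
    labs <- vapply(fit@design$blocks, function(b) b$label, "")
    ok <- TRUE
    for (l in c("MNC", "T", "Myeloid")) {
      bL <- fit@design$blocks[[match(paste0("decay.", l, ".LTR"), labs)]]
      bP <- fit@design$blocks[[match(paste0("decay.", l, ".PGK"), labs)]]
      tq <- min(bL$basis@boundary[2], bP$basis@boundary[2])
      ok <- ok && termEffect(fit, paste0("decay.", l, ".LTR"), tq) <
        termEffect(fit, paste0("decay.", l, ".PGK"), tq)
    }
    hit <- hit + ok
  }
  expect_gte(hit / nSeeds, 0.8)
})
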