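test_that("restricted LS equals the exhaustive active-set oracle", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(8:20, 1)
    p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    m <- sample(1:min(5, p + 1), 1)
    G <- matrix(rnorm(m * p), m, p)
    sol <- restrictedLS(y, X, G)
    orc <- activeSetOracle(y, X, G)
    expect_lt(max(abs(sol$theta - orc$theta)), 1e-6)
    expect_lt(sol$kkt["stationarity"], 1e-7)
    expect_lt(sol$kkt["violation"], 1e-9)
  }
})

test_that("interior solutions reduce to unconstrained least squares", {
  # noiseless data from a strictly increasing, strictly concave spline
  b <- splineBasis(c(0, 1), nInterior = 1, degree = 2)
  set.seed(2)
  x <- seq(0, 1, length.out = 40)
  betaTrue <- c(0, 0.5, 0.8, 0.9)  # strictly increasing, strictly concave
  y <- 1 + as.vector(evalBasis(b, x) %*% betaTrue)
  et <- data.frame(sample_id = paste0("s", 1:40), h = exp(y), log_h = y,
                   xvar = x)
  fit <- fitScs(et, scsModel(list(scsTerm("xvar", 1, saturation = FALSE))))
  des <- fit@design
  ols <- as.vector(solve(crossprod(des$X), crossprod(des$X, des$y)))
  expect_lt(max(abs(coef(fit) - ols)), 1e-6)
  expect_equal(length(fit@activeRows), 0L)
  expect_equal(faceDim(fit), ncol(des$X))
})

test_that("decreasing data under increasing constraints project to a constant", {
  x <- seq(0, 1, length.out = 30)
  y <- 3 - 2 * x
  et <- data.frame(sample_id = paste0("s", 1:30), h = exp(y), log_h = y,
                   xvar = x)
  fit <- fitScs(et, scsModel(list(scsTerm("xvar", 1, saturation = FALSE))))
  expect_lt(diff(range(fitted(fit))), 1e-8)
  expect_equal(unname(fitted(fit)[1]), mean(y), tolerance = 1e-8)
  # face reduces to the constant direction: only the intercept survives
  expect_equal(faceDim(fit), 1L)
})

test_that("variance estimator follows RSS/(n - 1.5 d)", {
  expect_equal(estimateVariance(rep(0, 10), 10, 2), 0)
  r <- c(1, 1, 1, 2)  # RSS = 7
  expect_equal(estimateVariance(r, 10, 2), 1)
  set.seed(6)
  for (i in 1:10) {
    r <- rnorm(30); d <- sample(1:10, 1)
    expect_equal(estimateVariance(r, 30, d), sum(r^2) / (30 - 1.5 * d))
  }
  expect_error(estimateVariance(rnorm(3), 3, 2), "exceed")
})

test_that("cone-face dimension is stable under row shuffling", {
  et <- makeSingleConfounderTable(n = 60, sigma = 0.15, seed = 9)
  model <- scsModel(list(scsTerm("xvar", 2)))
  fit <- fitScs(et, model)
  set.seed(10)
  for (i in 1:5) {
    perm <- sample(nrow(et))
    fitP <- fitScs(et[perm, ], model)
    expect_equal(faceDim(fitP), faceDim(fit))
    expect_lt(max(abs(sort(coef(fitP)) - sort(coef(fit)))), 1e-7)
  }
})

test_that("solution beats random feasible points", {
  set.seed(12)
  et <- makeSingleConfounderTable(n = 50, sigma = 0.2, seed = 13)
  fit <- fitScs(et, scsModel(list(scsTerm("xvar", 2))))
  des <- fit@design
  obj <- function(th) sum((des$y - des$X %*% th)^2)
  fstar <- obj(coef(fit))
  for (i in 1:1000) {
    th <- coef(fit) + rnorm(des$p, sd = 0.3)
    if (nrow(des$G) && min(des$G %*% th) < 0) next
    expect_gte(obj(th), fstar - 1e-10)
  }
})

test_that("shifting log-entropy by a constant only moves the intercept", {
  et <- makeSingleConfounderTable(n = 60, sigma = 0.1, seed = 14)
  model <- scsModel(list(scsTerm("xvar", 2)))
  f1 <- fitScs(et, model)
  et2 <- et
  et2$log_h <- et$log_h + 2.5
  et2$h <- exp(et2$log_h)
  f2 <- fitScs(et2, model)
  expect_equal(f2@beta0, f1@beta0 + 2.5, tolerance = 1e-7)
  keep <- setdiff(names(coef(f1)), "(Intercept)")
  expect_lt(max(abs(coef(f2)[keep] - coef(f1)[keep])), 1e-7)
  expect_equal(rescaleEntropies(f2) / rescaleEntropies(f1),
               setNames(rep(exp(2.5), 60), et$sample_id), tolerance = 1e-7)
})

test_that("fitted confounder effects satisfy their shape constraints", {
  set.seed(15)
  et <- simulateEntropyDataset(n = 150, seed = 16)
  fit <- fitScs(et, scsModel(list(scsTerm("dna_ng", 2), scsTerm("vcn", 2),
                                  scsTerm("sd", 2))))
  for (v in c("dna_ng", "vcn", "sd")) {
    g <- seq(min(et[[v]]), max(et[[v]]), length.out = 1000)
    e <- termEffect(fit, v, g)
    expect_gte(min(diff(e)), -1e-8)
    expect_lte(max(diff(e, differences = 2)), 1e-8)
    # saturation: analytic derivative vanishes at the right boundary
    blocks <- fit@design$blocks
    b <- blocks[[match(v, vapply(blocks, function(b) b$label, ""))]]
    d1 <- evalBasis(b$basis, max(g), deriv = 1) %*% b$map %*%
      coef(fit)[fit@design$colIdx[[v]]]
    expect_lt(abs(d1), 1e-8)
  }
})

test_that("rescaled entropies remove exactly the confounder contribution", {
  et <- simulateEntropyDataset(n = 80, seed = 17)
  fit <- fitScs(et, scsModel(list(scsTerm("dna_ng", 1), scsTerm("sd", 2))))
  hres <- rescaleEntropies(fit)
  expect_true(all(hres > 0))
  cc <- fit@design$confCols
  ceff <- as.vector(fit@design$X[, cc] %*% coef(fit)[cc])
  expect_equal(log(unname(hres)) - log(et$h), -ceff, tolerance = 1e-10)
})

test_that("design assembly validates metadata and rank", {
  et <- makeSingleConfounderTable(n = 30, seed = 18)
  expect_error(fitScs(et, scsModel(list(scsTerm("nope", 1)))), "nope")
  et2 <- et
  et2$xvar[4] <- NA
  expect_error(fitScs(et2, scsModel(list(scsTerm("xvar", 1)))), "non-finite")
  etDup <- et
  etDup$xcopy <- etDup$xvar
  expect_error(
    fitScs(etDup, scsModel(list(scsTerm("xvar", 1), scsTerm("xcopy", 1)))),
    "rank")
})
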