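test_that("V/W/Z have the documented difference patterns", {
  cm <- constraintMatrices(4)
  expect_equal(cm$Z[1, ], c(0, 0, -1, 1))
  expect_equal(cm$Z[2, ], c(-1, 2, -1, 0))
  expect_equal(cm$Z[3, ], c(0, -1, 2, -1))
  expect_equal(dim(cm$V), c(3, 4))
  expect_equal(dim(cm$W), c(2, 4))
  beta <- rep(2.5, 6)
  cm6 <- constraintMatrices(6)
  expect_equal(as.vector(cm6$V %*% beta), rep(0, 5))
  expect_equal(as.vector(cm6$W %*% beta), rep(0, 4))
  expect_error(constraintMatrices(2), "insufficient")
})

test_that("concavity plus the last monotonicity row implies full monotonicity", {
  # brute-force check of the constraint-reduction lemma
  set.seed(99)
  for (q in c(4, 5, 7)) {
    cm <- constraintMatrices(q)
    n <- 20000
    # sample the hypothesis region exactly: nonpositive second differences,
    # nonnegative last first-difference, free level; then CHECK that every
    # earlier first difference comes out nonnegative
    s <- -matrix(rexp(n * (q - 2)), n, q - 2)      # beta_j - 2beta_{j-1} + beta_{j-2}
    dLast <- rexp(n)                               # beta_q - beta_{q-1} >= 0
    d <- matrix(0, n, q - 1)                       # first differences d_2..d_q
    d[, q - 1] <- dLast
    for (j in (q - 1):2) d[, j - 1] <- d[, j] - s[, j - 1]
    beta <- rnorm(n) + t(apply(cbind(0, d), 1, cumsum))
    expect_true(all(abs(cm$W %*% t(beta) - t(-s)) < 1e-9))  # hypothesis holds
    expect_true(all(cm$V %*% t(beta) >= -1e-9))             # conclusion checked
  }
})

test_that("saturation transform pins the right-boundary derivative to zero", {
  b <- splineBasis(c(2, 9), nInterior = 2, degree = 2)
  A <- saturationTransform(b)
  expect_equal(dim(A), c(b@q, b@q - 1L))
  expect_equal(A[seq_len(b@q - 1L), ], diag(b@q - 1L))
  set.seed(5)
  d1R <- evalBasis(b, b@boundary[2], deriv = 1)
  for (i in 1:20) {
    betaStar <- rnorm(b@q - 1L)
    expect_lt(abs(d1R %*% (A %*% betaStar)), 1e-10)
  }
})

test_that("random feasible coefficients give monotone concave splines", {
  set.seed(21)
  b <- splineBasis(c(0, 1), nInterior = 3, degree = 2)
  q <- b@q
  nDraw <- 3000
  # feasible beta: nonincreasing nonnegative slopes, scaled by the actual
  # knot gaps attached to each coefficient
  kn <- b@knots
  gap <- vapply(2:q, function(j) kn[j + b@degree + 1] - kn[j], 0)
  slopes <- matrix(rexp(nDraw * (q - 1)), nDraw, q - 1)
  slopes <- t(apply(slopes, 1, function(v) sort(v, decreasing = TRUE)))
  incr <- sweep(slopes, 2, gap, `*`)
  beta <- cbind(0, t(apply(incr, 1, cumsum))) + rnorm(nDraw)
  cm <- basisConstraintMatrices(b)
  expect_true(all(cm$Z %*% t(beta) >= -1e-9))
  grid <- seq(0, 1, length.out = 1000)
  vals <- evalBasis(b, grid) %*% t(beta)
  d1 <- apply(vals, 2, diff)
  expect_gt(min(d1), -1e-8)
  d2 <- apply(vals, 2, function(v) diff(v, differences = 2))
  expect_lt(max(d2), 1e-8)
})

test_that("direction handling flips the design sign only, twice = identity", {
  b <- splineBasis(c(0, 1), nInterior = 1, degree = 2)
  up <- shapeConstraints(b, direction = "increasing")
  dn <- shapeConstraints(b, direction = "decreasing")
  expect_equal(applyDirection(up)$sign, 1)
  expect_equal(applyDirection(dn)$sign, -1)
  expect_equal(applyDirection(up)$M, applyDirection(dn)$M)
  expect_equal(-(-applyDirection(dn)$sign), applyDirection(dn)$sign)
})

test_that("decreasing fits have nonpositive first differences", {
  set.seed(8)
  x <- seq(0, 10, length.out = 60)
  et <- data.frame(sample_id = paste0("s", 1:60),
                   h = exp(2 - 0.15 * x), log_h = 2 - 0.15 * x, tvar = x)
  fit <- fitScs(et, scsModel(list(
    scsTerm("tvar", 1, direction = "decreasing", concave = FALSE,
            saturation = FALSE))))
  g <- seq(0, 10, length.out = 500)
  expect_lte(max(diff(termEffect(fit, "tvar", g))), 1e-9)
})

test_that("secondRight saturation makes the fit constant on the final interval", {
  b <- splineBasis(c(0, 12), nInterior = 2, degree = 2)
  cons <- shapeConstraints(b, monotone = TRUE, concave = FALSE,
                           saturation = TRUE, saturationAt = "secondRight")
  set.seed(4)
  distinct <- unique(b@knots)
  lastInt <- seq(distinct[length(distinct) - 1], distinct[length(distinct)],
                 length.out = 50)
  B <- evalBasis(b, lastInt)
  for (i in 1:10) {
    beta <- cons@A %*% rnorm(cons@qReduced)
    vals <- B %*% beta
    expect_lt(max(vals) - min(vals), 1e-10)
  }
})
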