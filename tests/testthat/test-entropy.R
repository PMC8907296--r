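test_that("Shannon entropy matches direct summation and closed forms", {
  expect_equal(shannonEntropy(c(1, 1, 1, 1)), log(4))
  expect_equal(shannonEntropy(5), 0)
  expect_equal(shannonEntropy(c(1, 1, 2)), 1.0397207708399179)
  set.seed(42)
  for (i in 1:20) {
    a <- rgamma(sample(2:50, 1), 1)
    expect_equal(shannonEntropy(a), entropyOracle(a))
  }
})

test_that("entropy is bounded by log(n), maximal iff uniform, scale invariant", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(2:30, 1)
    a <- runif(n)
    h <- shannonEntropy(a)
    expect_gte(h, 0)
    expect_lte(h, log(n) + 1e-12)
    expect_equal(shannonEntropy(a * runif(1, 0.1, 100)), h)
  }
  expect_equal(shannonEntropy(rep(3, 17)), log(17))
  expect_lt(shannonEntropy(c(10, rep(1, 16))), log(17))
})

test_that("zero abundances contribute nothing and invalid input errors", {
  expect_equal(shannonEntropy(c(1, 0, 1, 0, 2)), shannonEntropy(c(1, 1, 2)))
  expect_error(shannonEntropy(c(0, 0)), "zero")
  expect_error(shannonEntropy(c(1, -1)), "negative")
  expect_error(shannonEntropy(numeric()), "nonempty")
})

test_that("KL divergence matches summation and the uniform-reference identity", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(klDivergence(p, p), 0)
  expect_equal(klDivergence(c(0.5, 0.5), c(0.9, 0.1)), log(5 / 3))
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:20, 1)
    pr <- rgamma(n, 1); pr <- pr / sum(pr)
    u <- rep(1 / n, n)
    expect_equal(klDivergence(pr, u), log(n) - shannonEntropy(pr))
    expect_gte(klDivergence(pr, u), -1e-12)
  }
  expect_error(klDivergence(c(1, 0), c(0, 1)), "support")
  expect_error(klDivergence(c(0.5, 0.4), c(0.5, 0.5)), "sum to 1")
})

test_that("entropy tables compute per-sample entropy and drop single clones", {
  samples <- list(
    list(sample_id = "a", abundances = c(3, 3, 3), dna_ng = 5, vcn = 1, sd = 9L),
    list(sample_id = "b", abundances = c(10, 1), dna_ng = 20, vcn = 2, sd = 11L),
    list(sample_id = "c", abundances = c(1, 2, 3, 4), dna_ng = 100, vcn = 3, sd = 10L))
  tab <- buildEntropyTable(samples)
  expect_equal(nrow(tab), 3)
  expect_true(all(is.finite(tab$log_h)))
  expect_equal(tab$h, vapply(samples, function(s) entropyOracle(s$abundances), 0))
  expect_equal(tab$log_h, log(tab$h))
  expect_equal(tab$dna_ng, c(5, 20, 100))

  oneClone <- c(samples, list(list(sample_id = "mono", abundances = 7)))
  expect_warning(tab2 <- buildEntropyTable(oneClone), "mono")
  expect_equal(nrow(tab2), 3)
  expect_error(buildEntropyTable(oneClone, dropNonpositive = FALSE), "mono")
  expect_error(suppressWarnings(
    buildEntropyTable(list(list(sample_id = "x", abundances = 5)))), "no samples")
})
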