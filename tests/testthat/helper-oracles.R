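# Independent oracles, coded separately from the package internals.

# Plain summation Shannon entropy.
entropyOracle <- function(a) {
  p <- a[a > 0] / sum(a)
  s <- 0
  for (pi in p) s <- s - pi * log(pi)
  s
}

# Textbook recursive de Boor / Cox-de Boor B-spline basis value B_j^deg(x)
# on a full knot vector (0-based recursion on degree).
deBoorOracle <- function(knots, degree, j, x) {
  if (degree == 0) {
    # half-open intervals, closed at the right boundary
    hi <- knots[j + 1]
    isLast <- hi >= max(knots) && knots[j] < hi
    return(as.numeric(x >= knots[j] & (x < hi | (isLast && x <= hi))))
  }
  d1 <- knots[j + degree] - knots[j]
  d2 <- knots[j + degree + 1] - knots[j + 1]
  t1 <- if (d1 > 0) (x - knots[j]) / d1 * deBoorOracle(knots, degree - 1, j, x) else 0
  t2 <- if (d2 > 0) (knots[j + degree + 1] - x) / d2 *
          deBoorOracle(knots, degree - 1, j + 1, x) else 0
  t1 + t2
}

deBoorBasisRow <- function(knots, degree, x) {
  q <- length(knots) - degree - 1
  vapply(seq_len(q), function(j) deBoorOracle(knots, degree, j, x), 0)
}

# Exhaustive active-set oracle for min ||y - X theta||^2 s.t. G theta >= 0:
# solves the equality-restricted problem on every subset of constraint rows
# and returns the feasible solution with the smallest objective.
activeSetOracle <- function(y, X, G) {
  p <- ncol(X)
  H <- crossprod(X)
  cvec <- as.vector(crossprod(X, y))
  m <- nrow(G)
  best <- NULL
  nullspaceOf <- function(Amat) {
    if (nrow(Amat) == 0) return(diag(p))
    s <- svd(Amat, nu = 0, nv = p)
    r <- sum(s$d > max(dim(Amat)) * .Machine$double.eps * max(s$d))
    if (r >= p) matrix(0, p, 0) else s$v[, (r + 1):p, drop = FALSE]
  }
  for (mask in 0:(2^m - 1)) {
    act <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    N <- nullspaceOf(G[act, , drop = FALSE])
    th <- if (ncol(N) == 0) rep(0, p) else {
      NHN <- crossprod(N, H %*% N)
      if (rcond(NHN) < 1e-12) next
      as.vector(N %*% solve(NHN, crossprod(N, cvec)))
    }
    if (m > 0 && min(G %*% th) < -1e-9) next
    f <- sum((y - X %*% th)^2)
    if (is.null(best) || f < best$f - 1e-12) best <- list(theta = th, f = f)
  }
  best
}

# Exhaustive permutation distribution of the Spearman statistic
# S = sum (rank(x) - rank(y))^2, following the same two-sided convention as
# the exact test: double the attained tail of S.
spearmanPermOracle <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  sObs <- sum((rx - ry)^2)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  allS <- vapply(perms(ry), function(p) sum((rx - p)^2), 0)
  mid <- (n^3 - n) / 6
  p1 <- if (sObs > mid) mean(allS >= sObs - 1e-9) else mean(allS <= sObs + 1e-9)
  min(2 * p1, 1)
}

# Closed-form expected retained richness under rarefaction to depth t.
hyperRichnessOracle <- function(counts, t) {
  N <- sum(counts)
  sum(1 - exp(lchoose(N - counts, t) - lchoose(N, t)))
}

# A small entropy table with a single known Michaelis-Menten confounder.
makeSingleConfounderTable <- function(n = 80, a = 0.8, b = 20, sigma = 0.05,
                                      beta0 = 1, seed = 1) {
  set.seed(seed)
  x <- seq(1, 100, length.out = n)
  logh <- beta0 + a * x / (b + x) + rnorm(n, 0, sigma)
  data.frame(sample_id = paste0("S", seq_len(n)), h = exp(logh),
             log_h = logh, xvar = x)
}
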