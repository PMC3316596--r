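# mutual information estimators and discretization

test_that("discretization maps values to the expected bins", {
  expect_identical(discretizeProfile(c(0, 1, 2, 3), "equal-width", 2),
                   c(0L, 0L, 1L, 1L))
  expect_identical(discretizeProfile(c(10, 10, 10, 10), "equal-width", 2),
                   rep(0L, 4))
  labs <- discretizeProfile(c(5, 1, 3, 2, 4, 6), "equal-frequency", 3)
  expect_identical(unname(tabulate(labs + 1L, 3)), c(2L, 2L, 2L))
  # every finite value maps to exactly one bin in [0, nBins)
  for (s in 1:5) {
    x <- rnorm(50, sd = s)
    for (meth in c("equal-width", "equal-frequency")) {
      b <- discretizeProfile(x, meth, 4)
      expect_true(all(b >= 0L & b < 4L))
      expect_length(b, 50)
    }
  }
  expect_error(discretizeProfile(rep(1, 5), "equal-frequency", 2),
               "constant")
  expect_error(discretizeProfile(c(1, NA, 3), "equal-width", 2),
               "non-finite")
})

test_that("entropy estimators match hand-computed values and bounds", {
  expect_equal(binEntropy(c(5, 5, 5, 5)), log(4))
  expect_equal(binEntropy(c(4, 0, 0, 0)), 0)
  # miller-madow correction term on a hand example
  emp <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(binEntropy(c(3, 1), "miller-madow"), emp + 1 / 8)
  # schurmann-grassberger = plug-in on pseudocounted frequencies
  cnt <- c(3, 0, 1)
  psg <- (cnt + 1 / 3) / (sum(cnt) + 1)
  expect_equal(binEntropy(cnt, "schurmann-grassberger"),
               -sum(psg * log(psg)))
  expect_error(binEntropy(c(0, 0)), "at least 1")
  # bounded by log(K) plus the bias term
  set.seed(11)
  for (r in 1:20) {
    cnt <- rpois(6, 3) + c(1, rep(0, 5))
    for (est in c("empirical", "miller-madow", "shrinkage",
                  "schurmann-grassberger")) {
      h <- binEntropy(cnt, est)
      expect_gte(h, 0)
      expect_lte(h, log(6) + (6 - 1) / (2 * sum(cnt)) + 1e-12)
    }
  }
})

test_that("miller-madow dominates empirical; shrinkage interpolates", {
  set.seed(7)
  for (r in 1:50) {
    cnt <- rpois(8, 2) + c(1, rep(0, 7))
    expect_gte(binEntropy(cnt, "miller-madow"), binEntropy(cnt))
    # forced lambda = 0 reduces shrinkage to the empirical estimator
    expect_equal(binEntropy(cnt, "shrinkage", lambda = 0),
                 binEntropy(cnt))
    # forced lambda = 1 gives the uniform maximum
    expect_equal(binEntropy(cnt, "shrinkage", lambda = 1), log(8))
  }
  # degenerate variance denominator resolves to lambda = 1
  expect_equal(binEntropy(c(2, 2, 2, 2), "shrinkage"), log(4))
})

test_that("discrete MI obeys the self-information identity and symmetry", {
  set.seed(3)
  x <- rnorm(60)
  ests <- c("empirical", "miller-madow", "shrinkage",
            "schurmann-grassberger")
  # I(X, X) = H(X) for the empirical estimator, exactly
  bx <- discretizeProfile(x, "equal-width", 8)
  expect_equal(miDiscrete(x, x, "empirical", nBins = 8),
               binEntropy(tabulate(bx + 1L, 8)))
  for (est in ests) {
    y <- rnorm(60)
    expect_equal(miDiscrete(x, y, est), miDiscrete(y, x, est))
    expect_gte(miDiscrete(x, y, est), 0)
  }
  # hand-checkable toy: joint counts [[2,0],[0,2]] -> MI = log 2
  expect_equal(miDiscrete(c(1, 1, 5, 5), c(2, 2, 9, 9), "empirical",
                          nBins = 2), log(2))
  expect_error(miDiscrete(1:4, 1:5), "length")
})

test_that("independent profiles have near-zero empirical MI", {
  set.seed(19)
  x <- runif(5000)
  y <- runif(5000)
  # finite-sample MI bias grows ~ (nBins-1)^2 / (2n); at 10 bins it is
  # far below the 0.05 independence band
  expect_lt(miDiscrete(x, y, "empirical", nBins = 10), 0.05)
  expect_lt(miBspline(x, y), 0.05)
  expect_lt(miCorrelation(x, y), 0.05)
})

test_that("B-spline MI degenerates to hard binning at order 1 and scales to the Gaussian closed form", {
  p <- rhoPair(400, 0.5, seed = 21)
  expect_equal(miBspline(p$x, p$y, order = 1, nBins = 8),
               miDiscrete(p$x, p$y, "empirical", nBins = 8))
  # self-dependence is positive at any valid order
  for (k in 1:3) expect_gt(miBspline(p$x, p$x, order = k, nBins = 10), 0)
  # weights: partition of unity, up to `order` nonzero entries per sample
  W <- bagc3net:::.bsplineBasis(p$x, 3L, 10L)
  expect_equal(rowSums(W), rep(1, 400))
  expect_true(all(rowSums(W > 1e-12) <= 3))
  expect_true(all(W >= 0))
  # soft binning approaches the continuous closed form as bins grow
  p <- rhoPair(5000, 0.8, seed = 22)
  closed <- -0.5 * log(1 - 0.64)
  expect_lt(abs(miBspline(p$x, p$y, order = 3, nBins = 40) - closed), 0.05)
  expect_error(miBspline(p$x, p$y, order = 3, nBins = 2), "nBins")
})

test_that("correlation MI matches the analytic transform", {
  # rho = 0 exactly
  expect_equal(miCorrelation(c(-1, 0, 1), c(1, 0, 1)), 0)
  # perfectly linear: clamp keeps the value finite and large
  v <- miCorrelation(1:10, 1:10)
  expect_true(is.finite(v) && v > 12)
  # rho = 0.5 by construction: direct evaluation of the transform
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 10)
  r <- cor(x, y)
  expect_equal(miCorrelation(x, y), -0.5 * log(1 - r^2))
  # spearman on a monotone transform equals rank-perfect dependence
  expect_equal(miCorrelation(1:10, exp(1:10), "spearman"),
               miCorrelation(1:10, 1:10, "spearman"))
  expect_error(miCorrelation(rep(1, 5), 1:5), "constant")
})

test_that("MI matrix matches scalar calls entry-by-entry for every estimator", {
  set.seed(5)
  d <- noiseMatrix(5, 40, seed = 5)
  d[2, ] <- d[1, ] * 0.9 + rnorm(40, sd = 0.3)
  scalar <- list(
    pearson = function(x, y) miCorrelation(x, y, "pearson"),
    spearman = function(x, y) miCorrelation(x, y, "spearman"),
    kendall = function(x, y) miCorrelation(x, y, "kendall"),
    bspline = function(x, y) miBspline(x, y),
    empirical = function(x, y) miDiscrete(x, y, "empirical"),
    `miller-madow` = function(x, y) miDiscrete(x, y, "miller-madow"),
    shrinkage = function(x, y) miDiscrete(x, y, "shrinkage"),
    `schurmann-grassberger` =
      function(x, y) miDiscrete(x, y, "schurmann-grassberger"))
  for (est in names(scalar)) {
    M <- miMatrix(d, estimator = est)
    expect_true(all(M == t(M)))
    expect_true(all(M >= 0))
    expect_equal(unname(diag(M)), rep(0, 5))
    for (i in 1:4) for (j in (i + 1):5) {
      expect_equal(M[i, j], scalar[[est]](d[i, ], d[j, ]),
                   tolerance = 1e-10,
                   label = sprintf("%s (%d,%d)", est, i, j))
    }
  }
})

test_that("constant gene profiles get zero MI with a warning", {
  d <- noiseMatrix(4, 30, seed = 9)
  d[3, ] <- 7
  for (est in c("pearson", "bspline", "schurmann-grassberger")) {
    expect_warning(M <- miMatrix(d, estimator = est), "constant")
    expect_true(all(M[3, ] == 0) && all(M[, 3] == 0))
  }
})

test_that("pair count of computed entries is n(n-1)/2", {
  d <- noiseMatrix(7, 25, seed = 13)
  M <- miMatrix(d, estimator = "empirical")
  expect_identical(sum(upper.tri(M)), 21L)
  expect_true(all(is.finite(M)))
})
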