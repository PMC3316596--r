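#' Discretize a gene expression profile
#'
#' Maps a numeric profile to integer bin labels in `0 .. nBins-1`.
#' Equal-width binning partitions `[min, max]` into `nBins` intervals of
#' equal width, with the maximum assigned to the last bin; equal-frequency
#' binning places (up to integer rounding) the same number of samples in
#' every bin using rank-based quantile cut points.
#'
#' @param x numeric vector with at least two finite values.
#' @param method `"equal-width"` (default) or `"equal-frequency"`.
#' @param nBins number of bins, at least 2.
#' @return integer vector of bin labels in `[0, nBins)`.
#' @details A constant profile maps to a single bin under equal-width
#'   binning and is an error under equal-frequency binning (its quantiles
#'   are degenerate).
#' @examples
#' discretizeProfile(c(0, 1, 2, 3), "equal-width", 2)     # 0 0 1 1
#' discretizeProfile(c(5, 1, 3, 2, 4, 6), "equal-frequency", 3)
#' @export
discretizeProfile <- function(x, method = c("equal-width", "equal-frequency"),
                              nBins) {
  method <- match.arg(method)
  if (!is.numeric(x) || length(x) < 2L)
    stop("profile must be a numeric vector with at least two values")
  if (!all(is.finite(x)))
    stop("profile contains non-finite values")
  nBins <- as.integer(nBins)
  if (is.na(nBins) || nBins < 2L) stop("nBins must be an integer >= 2")
  if (method == "equal-width") {
    rng <- range(x)
    if (rng[1L] == rng[2L]) return(integer(length(x)))
    idx <- as.integer(floor((x - rng[1L]) / (rng[2L] - rng[1L]) * nBins))
    idx[idx >= nBins] <- nBins - 1L
    idx
  } else {
    if (min(x) == max(x))
      stop("constant profile cannot be discretized by equal-frequency binning")
    r <- rank(x, ties.method = "first")
    as.integer(ceiling(r * nBins / length(x))) - 1L
  }
}

.pluginEntropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# analytic James-Stein shrinkage weight toward the uniform target 1/K
.jsLambda <- function(p, N, K) {
  if (N <= 1) return(1)
  den <- (N - 1) * sum((1 / K - p)^2)
  if (den == 0) return(1)
  min(1, max(0, (1 - sum(p^2)) / den))
}

#' Entropy of bin counts
#'
#' Entropy (in nats) of a discretized variable from its observed cell
#' counts, under one of four estimators. `K` is the total number of cells,
#' `length(counts)`, including empty ones; `N = sum(counts)`.
#'
#' * `empirical` — plug-in: \eqn{-\sum_k (n_k/N) \ln(n_k/N)} over nonzero
#'   cells.
#' * `miller-madow` — empirical plus the bias correction
#'   \eqn{(\hat m - 1)/(2N)}, with \eqn{\hat m} the number of nonzero cells.
#' * `shrinkage` — plug-in applied to James-Stein-shrunk frequencies
#'   \eqn{\hat p_k = \lambda/K + (1-\lambda) n_k/N}, with the analytic
#'   optimal \eqn{\lambda} toward the uniform target, clamped to `[0, 1]`
#'   (\eqn{\lambda = 1} when the variance denominator vanishes).
#' * `schurmann-grassberger` — plug-in applied to Dirichlet-pseudocount
#'   frequencies \eqn{p_k = (n_k + 1/K)/(N + 1)}.
#'
#' @param counts nonnegative count vector (or matrix, for joint counts).
#' @param estimator estimator name, see above.
#' @param lambda optional fixed shrinkage weight overriding the analytic
#'   value (shrinkage estimator only); `lambda = 0` reproduces the
#'   empirical estimator.
#' @return entropy in nats.
#' @examples
#' binEntropy(c(5, 5, 5, 5))                      # log(4)
#' binEntropy(c(3, 1), "miller-madow")            # 0.5623 + 1/8
#' @export
binEntropy <- function(counts,
                       estimator = c("empirical", "miller-madow",
                                     "shrinkage", "schurmann-grassberger"),
                       lambda = NULL) {
  estimator <- match.arg(estimator)
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative")
  N <- sum(counts)
  if (N < 1) stop("total count must be at least 1")
  K <- length(counts)
  p <- counts / N
  switch(estimator,
    "empirical" = .pluginEntropy(p),
    "miller-madow" = .pluginEntropy(p) + (sum(counts > 0) - 1) / (2 * N),
    "shrinkage" = {
      lam <- if (is.null(lambda)) .jsLambda(p, N, K) else lambda
      if (lam < 0 || lam > 1) stop("lambda must lie in [0, 1]")
      .pluginEntropy(lam / K + (1 - lam) * p)
    },
    "schurmann-grassberger" = .pluginEntropy((counts + 1 / K) / (N + 1))
  )
}

#' Mutual information of two profiles from discretized data
#'
#' Estimates `I(X;Y) = H(X) + H(Y) - H(X,Y)` (nats) with all three
#' entropies computed by the same estimator on a shared `nBins x nBins`
#' grid; the result is clamped below at zero.
#'
#' @inheritParams binEntropy
#' @param x,y numeric vectors of equal length (>= 2).
#' @param method discretization method, see [discretizeProfile()].
#' @param nBins number of bins per margin; default
#'   `ceiling(sqrt(length(x)))` (at least 2).
#' @return MI in nats.
#' @examples
#' x <- rnorm(100)
#' miDiscrete(x, x)           # equals the marginal entropy of x
#' @export
miDiscrete <- function(x, y,
                       estimator = c("empirical", "miller-madow",
                                     "shrinkage", "schurmann-grassberger"),
                       method = "equal-width", nBins = NULL) {
  estimator <- match.arg(estimator)
  if (length(x) != length(y)) stop("x and y must have the same length")
  n <- length(x)
  if (n < 2L) stop("need at least two samples")
  if (is.null(nBins)) nBins <- max(2L, as.integer(ceiling(sqrt(n))))
  bx <- discretizeProfile(x, method, nBins)
  by <- discretizeProfile(y, method, nBins)
  joint <- tabulate(bx * nBins + by + 1L, nbins = nBins * nBins)
  hx <- binEntropy(tabulate(bx + 1L, nbins = nBins), estimator)
  hy <- binEntropy(tabulate(by + 1L, nbins = nBins), estimator)
  hxy <- binEntropy(joint, estimator)
  max(0, hx + hy - hxy)
}

# clamped uniform knot vector and Cox-de Boor recursion, vectorized over
# samples; returns an n x nBins weight matrix whose rows sum to 1
.bsplineBasis <- function(x, order, nBins) {
  M <- as.integer(nBins)
  k <- as.integer(order)
  n <- length(x)
  rng <- range(x)
  if (rng[1L] == rng[2L]) {
    W <- matrix(0, n, M)
    W[, 1L] <- 1
    return(W)
  }
  z <- (x - rng[1L]) / (rng[2L] - rng[1L]) * (M - k + 1)
  knots <- c(rep(0, k), seq_len(M - k), rep(M - k + 1, k))
  B <- matrix(0, n, M + k - 1L)
  for (i in seq_len(M + k - 1L)) {
    lo <- knots[i]
    hi <- knots[i + 1L]
    if (hi > lo) {
      inb <- z >= lo & z < hi
      if (hi == M - k + 1) inb <- inb | z == hi
      B[, i] <- as.numeric(inb)
    }
  }
  if (k > 1L) {
    for (ord in 2:k) {
      nb <- M + k - ord
      Bn <- matrix(0, n, nb)
      for (i in seq_len(nb)) {
        d1 <- knots[i + ord - 1L] - knots[i]
        d2 <- knots[i + ord] - knots[i + 1L]
        v <- numeric(n)
        if (d1 > 0) v <- v + (z - knots[i]) / d1 * B[, i]
        if (d2 > 0) v <- v + (knots[i + ord] - z) / d2 * B[, i + 1L]
        Bn[, i] <- v
      }
      B <- Bn
    }
  }
  B
}

#' B-spline mutual information estimator
#'
#' MI (nats) for continuous data: every sample contributes fractional
#' weights to up to `order` adjacent bins through B-spline basis functions
#' of the given order evaluated on range-scaled data, which reduces the
#' discretization bias for values near bin boundaries. The weighted
#' marginal and joint frequencies feed the empirical (plug-in) entropy
#' formula. `order = 1` degenerates to hard equal-width binning.
#'
#' @param x,y numeric vectors of equal length, at least `order` samples.
#' @param order spline order (polynomial degree + 1); default 3.
#' @param nBins number of bins, at least `order`; default 10.
#' @return MI in nats, clamped below at zero.
#' @export
miBspline <- function(x, y, order = 3L, nBins = 10L) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  order <- as.integer(order)
  nBins <- as.integer(nBins)
  if (order < 1L) stop("order must be >= 1")
  if (nBins < order) stop("nBins must be >= order")
  if (length(x) < order) stop("need at least `order` samples")
  n <- length(x)
  Wx <- .bsplineBasis(x, order, nBins)
  Wy <- .bsplineBasis(y, order, nBins)
  pxy <- crossprod(Wx, Wy) / n
  hx <- .pluginEntropy(colMeans(Wx))
  hy <- .pluginEntropy(colMeans(Wy))
  max(0, hx + hy - .pluginEntropy(as.vector(pxy)))
}

#' Correlation-based mutual information
#'
#' For jointly normal variables the MI and a correlation coefficient are in
#' exact correspondence: `I = -log(1 - rho^2) / 2`. The chosen coefficient
#' (Pearson, Spearman or Kendall) is plugged into this transform, with
#' `|rho|` clamped to `1 - 1e-12` so the result stays finite.
#'
#' @param x,y numeric vectors of equal length (>= 3), both non-constant.
#' @param coefficient `"pearson"` (default), `"spearman"` or `"kendall"`.
#' @return MI in nats.
#' @examples
#' miCorrelation(1:10, (1:10)^2, "spearman")   # rank-perfect dependence
#' @export
miCorrelation <- function(x, y,
                          coefficient = c("pearson", "spearman", "kendall")) {
  coefficient <- match.arg(coefficient)
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3L) stop("need at least three samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant profile")
  r <- stats::cor(x, y, method = coefficient)
  .corToMI(r)
}

.corToMI <- function(r) {
  r <- sign(r) * pmin(abs(r), 1 - 1e-12)
  -0.5 * log(1 - r^2)
}

.ESTIMATORS <- c("pearson", "spearman", "kendall", "bspline", "empirical",
                 "miller-madow", "shrinkage", "schurmann-grassberger")

# per-estimator engine: prep(x) builds a reusable per-profile representation,
# mi(r1, r2) the pairwise value. Used by the matrix and null-distribution
# code so each profile is processed once.
.miEngine <- function(estimator, n, nBins = NULL, order = 3L,
                      method = "equal-width") {
  estimator <- match.arg(estimator, .ESTIMATORS)
  if (estimator %in% c("pearson", "kendall")) {
    list(prep = identity,
         mi = function(a, b) {
           if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
           .corToMI(stats::cor(a, b, method = estimator))
         })
  } else if (estimator == "spearman") {
    list(prep = function(a) rank(a),
         mi = function(a, b) {
           if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
           .corToMI(stats::cor(a, b))
         })
  } else if (estimator == "bspline") {
    if (is.null(nBins)) nBins <- 10L
    list(prep = function(a) {
           W <- .bsplineBasis(a, order, nBins)
           list(W = W, h = .pluginEntropy(colMeans(W)))
         },
         mi = function(a, b) {
           pxy <- crossprod(a$W, b$W) / nrow(a$W)
           max(0, a$h + b$h - .pluginEntropy(as.vector(pxy)))
         })
  } else {
    if (is.null(nBins)) nBins <- max(2L, as.integer(ceiling(sqrt(n))))
    force(method)
    list(prep = function(a) {
           lab <- discretizeProfile(a, method, nBins)
           list(lab = lab,
                h = binEntropy(tabulate(lab + 1L, nbins = nBins), estimator))
         },
         mi = function(a, b) {
           joint <- tabulate(a$lab * nBins + b$lab + 1L,
                             nbins = nBins * nBins)
           max(0, a$h + b$h - binEntropy(joint, estimator))
         })
  }
}

#' Mutual information matrix over all gene pairs
#'
#' Computes the symmetric matrix of pairwise MI estimates for all
#' `n(n-1)/2` unordered gene pairs of an expression matrix — the first step
#' of MI-based network inference. Zero-variance (constant) gene profiles
#' get MI 0 against every partner, with a warning.
#'
#' @param data genes x samples numeric matrix (rownames = gene labels), or
#'   a `SummarizedExperiment` (first assay used).
#' @param estimator one of `"pearson"`, `"spearman"`, `"kendall"`,
#'   `"bspline"` (default), `"empirical"`, `"miller-madow"`, `"shrinkage"`,
#'   `"schurmann-grassberger"`.
#' @param nBins bins per margin for the discrete and B-spline estimators;
#'   defaults to `ceiling(sqrt(n_samples))` (discrete) or 10 (B-spline).
#' @param order B-spline order, default 3.
#' @param method discretization method for the discrete estimators.
#' @return symmetric nonnegative matrix with gene dimnames, zero diagonal,
#'   and the estimator recorded in `attr(, "estimator")`.
#' @export
miMatrix <- function(data, estimator = "bspline", nBins = NULL, order = 3L,
                     method = "equal-width") {
  data <- .exprMatrix(data)
  estimator <- match.arg(estimator, .ESTIMATORS)
  G <- nrow(data)
  n <- ncol(data)
  if (G < 2L || n < 2L) stop("need at least 2 genes and 2 samples")
  genes <- rownames(data)
  flat <- apply(data, 1L, function(r) max(r) == min(r))
  if (any(flat))
    warning(sprintf("%d constant gene profile(s) (%s): MI set to 0",
                    sum(flat),
                    paste(utils::head(genes[flat], 5L), collapse = ", ")))
  M <- matrix(0, G, G, dimnames = list(genes, genes))
  if (estimator %in% c("pearson", "spearman", "kendall")) {
    ok <- which(!flat)
    if (length(ok) >= 2L) {
      r <- stats::cor(t(data[ok, , drop = FALSE]), method = estimator)
      M[ok, ok] <- .corToMI(r)
    }
  } else if (estimator %in% c("bspline", "empirical")) {
    # weighted-frequency fast path: one big crossprod gives every pairwise
    # joint distribution as a block; empirical = indicator weights
    if (is.null(nBins)) {
      nBins <- if (estimator == "bspline") 10L
               else max(2L, as.integer(ceiling(sqrt(n))))
    }
    nBins <- as.integer(nBins)
    ord <- if (estimator == "bspline") as.integer(order) else 1L
    if (estimator == "empirical" && method == "equal-frequency") {
      eng <- .miEngine(estimator, n, nBins = nBins, method = method)
      M <- .miMatrixLoop(data, eng, flat, M)
    } else {
      W <- matrix(0, n, G * nBins)
      hx <- numeric(G)
      for (g in seq_len(G)) {
        Wg <- .bsplineBasis(data[g, ], ord, nBins)
        W[, (g - 1L) * nBins + seq_len(nBins)] <- Wg
        hx[g] <- .pluginEntropy(colMeans(Wg))
      }
      P <- crossprod(W) / n
      E <- P
      pos <- P > 0
      E[pos] <- P[pos] * log(P[pos])
      E[!pos] <- 0
      grp <- kronecker(diag(G), rep(1, nBins))
      Hj <- -crossprod(grp, E %*% grp)
      M <- outer(hx, hx, "+") - Hj
      M[M < 0] <- 0
      dimnames(M) <- list(genes, genes)
    }
  } else {
    eng <- .miEngine(estimator, n, nBins = nBins, method = method)
    M <- .miMatrixLoop(data, eng, flat, M)
  }
  M[flat, ] <- 0
  M[, flat] <- 0
  diag(M) <- 0
  M <- (M + t(M)) / 2   # enforce exact symmetry against round-off
  attr(M, "estimator") <- estimator
  M
}

.miMatrixLoop <- function(data, eng, flat, M) {
  G <- nrow(data)
  reps <- vector("list", G)
  for (g in seq_len(G)) {
    if (!flat[g]) reps[[g]] <- eng$prep(data[g, ])
  }
  for (i in seq_len(G - 1L)) {
    if (flat[i]) next
    for (j in (i + 1L):G) {
      if (flat[j]) next
      v <- tryCatch(eng$mi(reps[[i]], reps[[j]]),
                    error = function(e) {
                      stop(sprintf("MI failed for gene pair (%s, %s): %s",
                                   rownames(data)[i], rownames(data)[j],
                                   conditionMessage(e)), call. = FALSE)
                    })
      M[i, j] <- v
      M[j, i] <- v
    }
  }
  M
}
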